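#' Read a gene x sample count matrix from TSV
#'
#' Expects a `gene_id` first column and one column per sample.
#'
#' @param path TSV file path.
#' @return Numeric matrix with gene rownames.
#' @export
read_counts <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "gene_id") stop("first column must be `gene_id`",
                                     call. = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene_id
  storage.mode(m) <- "double"
  m
}

#' Read a sample sheet from TSV
#'
#' Columns `sample_id`, `timepoint`, `bio_rep`, `tech_rep`.
#'
#' @param path TSV file path.
#' @return A validated design tibble.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  check_design(tibble::as_tibble(d))
}

#' Read a long-form TMT peptide quantification table from TSV
#'
#' Columns `accession`, `gene_symbol`, `peptide_id` and the six reporter
#' columns of the channel scheme.
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_protein_quant <- function(path) {
  d <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  need <- c("accession", "gene_symbol", "peptide_id")
  if (!all(need %in% names(d)))
    stop("protein table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  d
}

#' Read a gene -> GO term annotation map from TSV
#'
#' Columns `gene_symbol`, `term_id`, `term_name`, `category`.
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_annotations <- function(path) {
  d <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  need <- c("gene_symbol", "term_id", "term_name", "category")
  if (!all(need %in% names(d)))
    stop("annotation table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  d
}

# Deterministic TSV writer used by all output stages.
write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a count matrix as TSV
#'
#' @param counts Gene x sample matrix.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  d <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write_tsv_plain(d, path)
}

#' Path to a packaged synthetic fixture file
#'
#' The package ships a small seed-fixed synthetic dataset (200 genes x
#' 12 samples, 60 proteins, 30 GO-style terms, plus per-layer truth
#' tables) for deterministic examples and tests.
#'
#' @param file File name under `extdata`, e.g. `"fixture_counts.tsv"`;
#'   empty to list available files.
#' @return File path (or vector of file names).
#' @export
fixture_path <- function(file = "") {
  if (nzchar(file))
    system.file("extdata", file, package = "neurodevomics", mustWork = TRUE)
  else
    dir(system.file("extdata", package = "neurodevomics"))
}

#' Load the packaged synthetic fixture dataset
#'
#' @return A list with `counts`, `design`, `rna_truth`, `proteins`,
#'   `protein_truth`, `annotations`, `annotation_truth`, `contaminants`.
#' @export
load_fixture <- function() {
  list(
    counts = read_counts(fixture_path("fixture_counts.tsv")),
    design = read_design(fixture_path("fixture_samples.tsv")),
    rna_truth = tibble::as_tibble(
      utils::read.delim(fixture_path("fixture_rna_truth.tsv"))),
    proteins = read_protein_quant(fixture_path("fixture_proteins.tsv")),
    protein_truth = tibble::as_tibble(
      utils::read.delim(fixture_path("fixture_protein_truth.tsv"))),
    annotations = read_annotations(fixture_path("fixture_annotations.tsv")),
    annotation_truth = tibble::as_tibble(
      utils::read.delim(fixture_path("fixture_annotation_truth.tsv"))),
    contaminants = readLines(fixture_path("fixture_contaminants.txt"))
  )
}
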