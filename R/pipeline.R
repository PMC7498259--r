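#' Pipeline run configuration
#'
#' Validated bundle of inputs, thresholds and the seed for [run_all()].
#' Defaults are the study's printed thresholds: detection filter 5
#' samples, FDR 0.05, QC cascade 3 peptides / 100% variability / 0.4
#' replicate discordance, regulation call 0.3 log2 units, k = 6 clusters.
#'
#' @param counts,samples,proteins,annotations Input TSV paths; leave
#'   `NULL` and supply `sim` to simulate inputs instead.
#' @param contaminants Character vector of contaminant accession
#'   patterns, or a path to a plain-text file with one pattern per line.
#' @param outdir Output directory (created if missing).
#' @param sim Optional [sim_config()]; when given, all inputs are
#'   simulated into `outdir` and then analyzed.
#' @param alpha FDR threshold for DE calls.
#' @param min_samples Detection filter threshold.
#' @param min_peptides,max_variability,max_replicate_discordance QC
#'   thresholds.
#' @param reg_threshold Regulation |log2FC| threshold.
#' @param k Number of protein clusters.
#' @param scale RNA modeling scale, `"rpm"` or `"log2"`.
#' @param bh_family Enrichment BH family policy.
#' @param top_terms Rows per enrichment report.
#' @param seed Integer seed for every stochastic step.
#' @return A list of class `run_config`.
#' @export
run_config <- function(counts = NULL, samples = NULL, proteins = NULL,
                       annotations = NULL, contaminants = c("^CON_"),
                       outdir = tempfile("ndo_run_"), sim = NULL,
                       alpha = 0.05, min_samples = 5, min_peptides = 3,
                       max_variability = 100, max_replicate_discordance = 0.4,
                       reg_threshold = 0.3, k = 6,
                       scale = c("rpm", "log2"),
                       bh_family = c("per_category", "pooled"),
                       top_terms = 10, seed = 1L) {
  scale <- match.arg(scale)
  bh_family <- match.arg(bh_family)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)",
                                     call. = FALSE)
  if (min_samples < 1) stop("`min_samples` must be >= 1", call. = FALSE)
  if (min_peptides < 0 || max_variability < 0 ||
      max_replicate_discordance < 0 || reg_threshold < 0)
    stop("QC and regulation thresholds must be nonnegative", call. = FALSE)
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  if (is.null(sim) &&
      (is.null(counts) || is.null(samples) || is.null(proteins) ||
         is.null(annotations)))
    stop("either supply all input paths or a `sim` config", call. = FALSE)
  if (length(contaminants) == 1 && file.exists(contaminants))
    contaminants <- readLines(contaminants)
  structure(list(
    counts = counts, samples = samples, proteins = proteins,
    annotations = annotations, contaminants = contaminants,
    outdir = outdir, sim = sim, alpha = alpha, min_samples = min_samples,
    min_peptides = min_peptides, max_variability = max_variability,
    max_replicate_discordance = max_replicate_discordance,
    reg_threshold = reg_threshold, k = k, scale = scale,
    bh_family = bh_family, top_terms = top_terms, seed = as.integer(seed)),
    class = "run_config")
}

stage_msg <- function(...) message("[neurodevomics] ", ...)

#' Run the full pipeline
#'
#' Executes simulate (optional) -> RNA-seq differential expression ->
#' proteomics QC + clustering -> GO enrichment of the up- and
#' downregulated gene lists -> RNA-protein integration, writing every
#' intermediate table under `config$outdir` plus a JSON manifest with
#' the seed, parameters, per-stage row counts and MD5 checksums of all
#' outputs. Reruns with the same inputs and seed are byte-identical.
#'
#' @param config A [run_config()].
#' @return The manifest (list), invisibly written to
#'   `manifest.json`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  counts_n <- list()

  if (!is.null(config$sim)) {
    stage_msg("simulate: generating synthetic inputs")
    sim <- config$sim
    rna <- simulate_counts(sim)
    tmt <- simulate_tmt(sim)
    ann <- simulate_annotations(sim, rna$truth$gene_id, rna$truth$is_de)
    write_counts(rna$counts, out("sim_counts.tsv"))
    write_tsv_plain(rna$design, out("sim_samples.tsv"))
    write_tsv_plain(rna$truth, out("sim_rna_truth.tsv"))
    write_tsv_plain(tmt$records, out("sim_proteins.tsv"))
    write_tsv_plain(tmt$truth, out("sim_protein_truth.tsv"))
    write_tsv_plain(ann$annotations, out("sim_annotations.tsv"))
    counts <- rna$counts; design <- rna$design
    proteins <- tmt$records; annotations <- ann$annotations
  } else {
    stage_msg("load: reading inputs")
    counts <- read_counts(config$counts)
    design <- read_design(config$samples)
    proteins <- read_protein_quant(config$proteins)
    annotations <- read_annotations(config$annotations)
  }
  counts_n$genes_in <- nrow(counts)
  counts_n$samples <- nrow(design)
  counts_n$peptide_rows_in <- nrow(proteins)

  stage_msg("rnaseq: nested ANOVA / Tukey / BH on ", nrow(counts), " genes")
  de <- run_rnaseq_de(counts, design, min_samples = config$min_samples,
                      alpha = config$alpha, scale = config$scale)
  write_tsv_plain(de$results, out("rna_results.tsv"))
  writeLines(de$removed, out("rna_removed_genes.txt"))
  calls <- call_de(de$results, alpha = config$alpha, pair = "d7_d1")
  counts_n$genes_filtered <- length(de$removed)
  counts_n$genes_kept <- nrow(counts) - length(de$removed)
  counts_n$genes_up_d7_d1 <- length(calls$up)
  counts_n$genes_down_d7_d1 <- length(calls$down)

  stage_msg("proteome: QC cascade and clustering")
  prot <- run_proteomics(
    proteins, contaminants = config$contaminants,
    min_peptides = config$min_peptides,
    max_variability = config$max_variability,
    max_replicate_discordance = config$max_replicate_discordance,
    threshold = config$reg_threshold, k = config$k, seed = config$seed)
  write_tsv_plain(prot$profiles, out("protein_profiles.tsv"))
  write_tsv_plain(prot$excluded, out("protein_exclusions.tsv"))
  write_tsv_plain(prot$replicate_correlation,
                  out("protein_replicate_correlation.tsv"))
  counts_n$proteins_quantified <- nrow(prot$profiles)
  counts_n$proteins_contaminant <- length(prot$contaminants_removed)
  counts_n$proteins_qc_excluded <- nrow(prot$excluded)
  counts_n$proteins_regulated <- sum(prot$profiles$regulated)

  stage_msg("enrich: hypergeometric GO over-representation")
  kept_genes <- rownames(de$rpm)
  universe <- intersect(kept_genes, unique(annotations$gene_symbol))
  enr <- list()
  for (dirn in c("up", "down")) {
    q <- intersect(calls[[dirn]], universe)
    enr[[dirn]] <- if (length(q) > 0)
      enrich(q, annotations, universe, bh_family = config$bh_family)
    else tibble::tibble()
    write_tsv_plain(enr[[dirn]], out(sprintf("enrichment_%s.tsv", dirn)))
  }
  counts_n$enrichment_universe <- length(universe)

  stage_msg("integrate: matching layers by gene symbol")
  rna_fc <- rna_log2fc(de$rpm, design)
  passing <- prot$profiles[prot$profiles$qc_pass, , drop = FALSE]
  integ <- tryCatch(run_integration(rna_fc, passing), error = function(e) {
    stage_msg("integrate skipped: ", conditionMessage(e))
    NULL
  })
  if (!is.null(integ)) {
    write_tsv_plain(integ$records, out("integration.tsv"))
    jsonlite::write_json(integ$summary, out("integration_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    counts_n$integration_matched <- integ$summary$n_matched
  }

  files <- setdiff(dir(config$outdir), "manifest.json")
  manifest <- list(
    package = "neurodevomics",
    version = as.character(utils::packageVersion("neurodevomics")),
    seed = config$seed,
    parameters = config[c("alpha", "min_samples", "min_peptides",
                          "max_variability", "max_replicate_discordance",
                          "reg_threshold", "k", "scale", "bh_family")],
    counts = counts_n,
    checksums = as.list(tools::md5sum(file.path(config$outdir, sort(files))))
  )
  names(manifest$checksums) <- sort(files)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
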