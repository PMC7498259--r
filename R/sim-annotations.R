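#' Simulate GO-style gene annotations with planted enriched terms
#'
#' Draws `n_terms` terms across the three GO categories (CC, BP, MF),
#' each annotating a random gene set from the supplied universe. For the
#' planted enriched terms, member genes are sampled with weight
#' `enriched_odds_ratio` on DE-flagged genes, so the terms are genuinely
#' over-represented in the DE set; an odds ratio of 1 plants nothing.
#'
#' @param config A [sim_config()].
#' @param gene_ids Character vector: the gene universe.
#' @param de_flags Logical vector parallel to `gene_ids` marking the DE
#'   genes that enriched terms over-sample.
#' @return A list with `annotations` (tibble: `gene_symbol`, `term_id`,
#'   `term_name`, `category`) and `truth` (tibble: `term_id`, `category`,
#'   `planted_enriched`).
#' @export
simulate_annotations <- function(config, gene_ids, de_flags = NULL) {
  validate_sim_config(config)
  if (length(gene_ids) == 0) stop("empty gene universe", call. = FALSE)
  if (is.null(de_flags)) de_flags <- rep(FALSE, length(gene_ids))
  stopifnot(length(de_flags) == length(gene_ids))
  set.seed(config$seed + 2L)

  n_t <- config$n_terms
  term_id <- sprintf("GO:%07d", seq_len(n_t))
  category <- sample(c("CC", "BP", "MF"), n_t, replace = TRUE)
  sizes <- sample(seq(config$term_size_range[1], config$term_size_range[2]),
                  n_t, replace = TRUE)
  sizes <- pmin(sizes, length(gene_ids))
  or <- config$enriched_odds_ratio
  n_enr <- if (or > 1 && any(de_flags)) min(config$n_enriched_terms, n_t) else 0L
  enriched <- seq_len(n_t) <= n_enr  # first terms; identity is arbitrary

  members <- lapply(seq_len(n_t), function(i) {
    w <- if (enriched[i]) ifelse(de_flags, or, 1) else rep(1, length(gene_ids))
    sort(sample(gene_ids, sizes[i], prob = w))
  })
  ann <- tibble::tibble(
    gene_symbol = unlist(members),
    term_id = rep(term_id, lengths(members)),
    term_name = rep(sprintf("synthetic term %d", seq_len(n_t)),
                    lengths(members)),
    category = rep(category, lengths(members))
  )
  truth <- tibble::tibble(term_id = term_id, category = category,
                          planted_enriched = enriched)
  list(annotations = ann, truth = truth)
}

#' Link RNA and protein layers with a controlled true correlation
#'
#' Assigns shared gene symbols between the two omics layers and draws the
#' paired day7/day1 log2 fold-changes from a bivariate construction with
#' true correlation `rho_rna_protein`: the protein value is
#' `rho * x + sqrt(1 - rho^2) * z` with `z` independent standard normal,
#' so at `rho = 1` the two layers are identical. The RNA-side values are
#' taken from `rna_lfc` when supplied (e.g. the planted truth of
#' [simulate_counts()]) and drawn standard normal otherwise. A fraction
#' `unshared_fraction` of symbols is present in only one layer and is
#' excluded from the pairing.
#'
#' @param config A [sim_config()].
#' @param rna_lfc Optional numeric vector of RNA log2 fold-changes to use
#'   as the RNA marginal (standardized internally when `rho < 1`).
#' @return A tibble with `gene_symbol`, `rna_log2fc`, `prot_log2fc`,
#'   `shared` (logical; unshared symbols carry `NA` in the missing layer).
#' @export
link_omics <- function(config, rna_lfc = NULL) {
  validate_sim_config(config)
  rho <- config$rho_rna_protein
  set.seed(config$seed + 3L)
  n_total <- min(config$n_genes, config$n_proteins)
  n_shared <- round((1 - config$unshared_fraction) * n_total)

  x <- if (is.null(rna_lfc)) stats::rnorm(n_total) else {
    if (length(rna_lfc) < n_total)
      stop("`rna_lfc` shorter than the linked layer", call. = FALSE)
    rna_lfc[seq_len(n_total)]
  }
  if (abs(rho) < 1) {
    xs <- if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x
    y <- rho * xs + sqrt(1 - rho^2) * stats::rnorm(n_total)
  } else {
    y <- sign(rho) * x
  }
  shared <- seq_len(n_total) <= n_shared
  tibble::tibble(
    gene_symbol = sprintf("GENE%05d", seq_len(n_total)),
    rna_log2fc = ifelse(shared | seq_len(n_total) %% 2 == 0, x, NA_real_),
    prot_log2fc = ifelse(shared | seq_len(n_total) %% 2 == 1, y, NA_real_),
    shared = shared
  )
}
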