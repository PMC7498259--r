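#' Hypergeometric upper-tail enrichment p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` annotated genes in a query of size `n` from a
#' universe of `N` genes of which `K` carry the annotation. Computed via
#' the stable log-space tail of `stats::phyper`.
#'
#' @param k Observed overlap between query and term.
#' @param K Genes in the universe annotated to the term.
#' @param n Query size.
#' @param N Universe size.
#' @return Upper-tail probability; `k = 0` gives exactly 1. Vectorized.
#' @export
hypergeom_test <- function(k, K, n, N) {
  if (any(K < 0 | K > N) || any(n < 0 | n > N))
    stop("need 0 <= K <= N and 0 <= n <= N", call. = FALSE)
  if (any(k < 0 | k > pmin(K, n)))
    stop("need 0 <= k <= min(K, n)", call. = FALSE)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis against GO-style annotations
#'
#' One hypergeometric test per term, with `K` computed against the
#' supplied universe, BH adjustment per category (CC/BP/MF panels are
#' separate families by default; `bh_family = "pooled"` uses one family),
#' and results sorted by adjusted then raw p. Terms with fewer than
#' `min_term_size` universe genes are untestable and skipped.
#'
#' @param query Character vector of gene symbols (genes of interest).
#'   Genes outside the universe are dropped with a warning.
#' @param annotations Tibble with `gene_symbol`, `term_id`, `term_name`,
#'   `category`.
#' @param universe Character vector: the background gene set.
#' @param min_term_size Minimum `K` for a term to be tested, default 2.
#' @param bh_family `"per_category"` (default) or `"pooled"`.
#' @param top Optional integer: report only the `top` rows after sorting.
#' @return A tibble with `term_id`, `term_name`, `category`, `k`, `K`,
#'   `n`, `N`, `p`, `p_adj`, sorted by `p_adj` then `p`.
#' @export
enrich <- function(query, annotations, universe, min_term_size = 2,
                   bh_family = c("per_category", "pooled"), top = NULL) {
  bh_family <- match.arg(bh_family)
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  query <- unique(query)
  if (length(query) == 0) stop("empty query", call. = FALSE)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
    if (length(query) == 0) stop("no query genes in the universe",
                                 call. = FALSE)
  }
  ann <- annotations[annotations$gene_symbol %in% universe, , drop = FALSE]
  if (nrow(ann) == 0) stop("no annotations overlap the universe",
                           call. = FALSE)
  N <- length(universe)
  n <- length(query)
  g <- dplyr::group_by(ann, .data$term_id, .data$term_name, .data$category)
  res <- dplyr::summarise(
    g,
    K = dplyr::n_distinct(.data$gene_symbol),
    k = dplyr::n_distinct(intersect(.data$gene_symbol, query)),
    .groups = "drop")
  res <- res[res$K >= min_term_size, , drop = FALSE]
  res$n <- n
  res$N <- N
  res$p <- hypergeom_test(res$k, res$K, res$n, res$N)
  if (bh_family == "per_category") {
    res <- dplyr::group_by(res, .data$category)
    res <- dplyr::mutate(res, p_adj = adjust_bh(.data$p))
    res <- dplyr::ungroup(res)
  } else {
    res$p_adj <- adjust_bh(res$p)
  }
  res <- res[order(res$p_adj, res$p, res$term_id), ]
  res <- res[, c("term_id", "term_name", "category", "k", "K", "n", "N",
                 "p", "p_adj")]
  if (!is.null(top)) res <- utils::head(res, top)
  res
}
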