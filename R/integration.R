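#' Marker panel used in the study's figures
#'
#' Typical stem-cell, neuron and axon markers highlighted in the
#' transcriptome/proteome comparison.
#'
#' @return A named character vector (names = marker class).
#' @export
neuro_marker_panel <- function() {
  c(stem = "NOTCH1", stem = "SOX2", stem = "MKI67", stem = "LIN28A",
    stem = "OTX2", stem = "NES",
    neuron = "DCX", neuron = "ENO2", neuron = "SYP", neuron = "MAP2",
    neuron = "STMN1", neuron = "TUBB3",
    axon = "TRIM46", axon = "MAPT", axon = "BASP1", axon = "ANK3",
    axon = "NCAM1", axon = "GAP43", axon = "NFASC")
}

#' Match RNA and protein layers by gene symbol
#'
#' Inner join on upper-cased gene symbol. Duplicate symbols within a
#' layer are collapsed first: transcripts sharing a symbol are summed on
#' the linear scale (when `mean_earlier`/`mean_later` columns are
#' available, e.g. from [rna_log2fc()]) and the fold-change recomputed;
#' proteins sharing a symbol keep the entry with the most peptides.
#'
#' @param rna Tibble with `gene_symbol` and `log2fc` (day7/day1),
#'   optionally `mean_earlier` and `mean_later` for duplicate collapse.
#' @param prot Tibble with `gene_symbol`, a log2 fold-change column
#'   (`log2fc` or `mean_l2_d7_d1`), optionally `n_peptides`.
#' @return A tibble with `gene_symbol`, `rna_log2fc`, `prot_log2fc`,
#'   `concordant`; attributes `n_rna_collapsed` / `n_prot_collapsed`
#'   count removed duplicates.
#' @export
match_layers <- function(rna, prot) {
  rna$gene_symbol <- toupper(rna$gene_symbol)
  prot$gene_symbol <- toupper(prot$gene_symbol)

  n_rna_dup <- nrow(rna) - dplyr::n_distinct(rna$gene_symbol)
  if (n_rna_dup > 0) {
    if (all(c("mean_earlier", "mean_later") %in% names(rna))) {
      g <- dplyr::group_by(rna, .data$gene_symbol)
      rna <- dplyr::summarise(g,
        mean_earlier = sum(.data$mean_earlier),
        mean_later = sum(.data$mean_later),
        log2fc = log2((sum(.data$mean_later) + 1) /
                        (sum(.data$mean_earlier) + 1)),
        .groups = "drop")
    } else {
      g <- dplyr::group_by(rna, .data$gene_symbol)
      rna <- dplyr::summarise(g, log2fc = mean(.data$log2fc),
                              .groups = "drop")
    }
  }

  if (!"log2fc" %in% names(prot)) {
    if (!"mean_l2_d7_d1" %in% names(prot))
      stop("protein layer needs `log2fc` or `mean_l2_d7_d1`", call. = FALSE)
    prot$log2fc <- prot$mean_l2_d7_d1
  }
  n_prot_dup <- nrow(prot) - dplyr::n_distinct(prot$gene_symbol)
  if (n_prot_dup > 0) {
    ord <- if ("n_peptides" %in% names(prot))
      order(-prot$n_peptides) else seq_len(nrow(prot))
    prot <- prot[ord, ]
    prot <- prot[!duplicated(prot$gene_symbol), ]
  }

  shared <- intersect(rna$gene_symbol, prot$gene_symbol)
  if (length(shared) == 0)
    stop("no shared gene symbols between the layers (",
         dplyr::n_distinct(rna$gene_symbol), " RNA vs ",
         dplyr::n_distinct(prot$gene_symbol), " protein symbols)",
         call. = FALSE)
  out <- tibble::tibble(
    gene_symbol = sort(shared),
    rna_log2fc = rna$log2fc[match(sort(shared), rna$gene_symbol)],
    prot_log2fc = prot$log2fc[match(sort(shared), prot$gene_symbol)])
  out$concordant <- concordant_pair(out$rna_log2fc, out$prot_log2fc)
  attr(out, "n_rna_collapsed") <- n_rna_dup
  attr(out, "n_prot_collapsed") <- n_prot_dup
  out
}

# Sign concordance with a snap-to-zero guard: values within 1e-12 of 0
# count as zero and are concordant only with another exact zero.
concordant_pair <- function(x, y) {
  sx <- sign(x) * (abs(x) > 1e-12)
  sy <- sign(y) * (abs(y) > 1e-12)
  (sx == sy & sx != 0) | (sx == 0 & sy == 0)
}

#' Pearson correlation between matched RNA and protein fold-changes
#'
#' @param records Matched records from [match_layers()].
#' @return A list with `r`, `p` (two-sided, t transform), `n`.
#' @export
correlate_layers <- function(records) {
  ok <- is.finite(records$rna_log2fc) & is.finite(records$prot_log2fc)
  x <- records$rna_log2fc[ok]
  y <- records$prot_log2fc[ok]
  if (length(x) < 3) stop("need at least 3 matched records", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a layer", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Trend concordance between the omics layers
#'
#' Counts matched genes whose RNA and protein day7/day1 fold-changes
#' share the same sign.
#'
#' @param records Matched records from [match_layers()].
#' @return A list with `count` and `fraction`.
#' @export
concordance <- function(records) {
  if (nrow(records) == 0) stop("no records", call. = FALSE)
  conc <- concordant_pair(records$rna_log2fc, records$prot_log2fc)
  list(count = sum(conc), fraction = mean(conc))
}

#' Hierarchical ordering of marker rows for heatmap export
#'
#' Agglomerative clustering of the requested marker rows with Euclidean
#' distance and average linkage; the returned leaf order is the
#' deterministic `stats::hclust` order.
#'
#' @param mat Numeric matrix of relative expressions, rownames = gene
#'   symbols.
#' @param markers Character vector of marker symbols; unknown symbols are
#'   dropped with a warning.
#' @return A list with `order` (ordered marker symbols), `hclust` (the
#'   tree) and `matrix` (the reordered submatrix).
#' @export
order_markers <- function(mat, markers = neuro_marker_panel()) {
  known <- markers[markers %in% rownames(mat)]
  if (length(known) < length(markers))
    warning(length(markers) - length(known),
            " marker symbol(s) not in the matrix dropped")
  if (length(known) < 2) stop("need at least 2 markers present",
                              call. = FALSE)
  sub <- mat[known, , drop = FALSE]
  hc <- stats::hclust(stats::dist(sub, method = "euclidean"),
                      method = "average")
  list(order = rownames(sub)[hc$order], hclust = hc,
       matrix = sub[hc$order, , drop = FALSE])
}

#' Integration stage summary
#'
#' Matches layers, computes the Pearson correlation and the trend
#' concordance.
#'
#' @inheritParams match_layers
#' @return A list with `records`, `summary` (list: `n_matched`, `r`,
#'   `p`, `concordant_count`, `concordant_fraction`).
#' @export
run_integration <- function(rna, prot) {
  records <- match_layers(rna, prot)
  corr <- correlate_layers(records)
  conc <- concordance(records)
  list(records = records,
       summary = list(n_matched = nrow(records), r = corr$r, p = corr$p,
                      concordant_count = conc$count,
                      concordant_fraction = conc$fraction))
}
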