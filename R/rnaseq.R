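#' Reads-per-million normalization
#'
#' Scales every sample (column) so its total is one million:
#' `rpm[g, s] = counts[g, s] / sum(counts[, s]) * 1e6`. Run before any
#' gene filtering so that column totals reflect the full library.
#'
#' @param counts Numeric gene x sample matrix with nonnegative values and
#'   unique rownames (gene ids).
#' @return A matrix of the same shape in RPM units.
#' @export
normalize_rpm <- function(counts) {
  counts <- as.matrix(counts)
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids", call. = FALSE)
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    bad <- colnames(counts)[totals <= 0]
    stop("sample(s) with non-positive column total: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sweep(counts, 2, totals, `/`) * 1e6
}

#' Filter genes detected in too few samples
#'
#' Keeps genes observed (nonzero) in at least `min_samples` samples;
#' "observed" is evaluated on the matrix given, conventionally the raw
#' counts. The study default excludes genes seen in fewer than five of
#' the twelve samples.
#'
#' @param mat Gene x sample matrix (counts or RPM).
#' @param min_samples Minimum number of samples with a nonzero value.
#' @return A list with `kept` (filtered matrix) and `removed` (character
#'   vector of dropped gene ids).
#' @export
filter_low_detection <- function(mat, min_samples = 5) {
  stopifnot(min_samples >= 1)
  mat <- as.matrix(mat)
  if (min_samples > ncol(mat))
    warning("`min_samples` exceeds the number of samples; all genes removed")
  detected <- rowSums(mat != 0)
  keep <- detected >= min_samples
  list(kept = mat[keep, , drop = FALSE],
       removed = rownames(mat)[!keep])
}

# Model matrices for the nested-replicate design:
# expression ~ timepoint + bio_rep + tech_rep nested in bio_rep.
de_design_matrices <- function(design) {
  design <- check_design(design)
  x_full <- stats::model.matrix(~ timepoint + bio_rep + bio_rep:tech_rep,
                                data = design)
  x_red <- stats::model.matrix(~ bio_rep + bio_rep:tech_rep, data = design)
  qr_full <- qr(x_full)
  qr_red <- qr(x_red)
  df_tp <- qr_full$rank - qr_red$rank
  df_res <- nrow(design) - qr_full$rank
  if (df_tp < 1) stop("design is rank-deficient for the timepoint factor",
                      call. = FALSE)
  if (df_res < 1) stop("design leaves no residual degrees of freedom",
                       call. = FALSE)
  list(design = design, qr_full = qr_full, qr_red = qr_red,
       df_tp = df_tp, df_res = df_res)
}

#' Fit the nested-replicate ANOVA model to one or many genes
#'
#' Ordinary least squares of expression on
#' `timepoint + bio_rep + tech_rep` (technical replicate nested within
#' biological replicate), fitted to all genes at once by projection onto
#' the full and the timepoint-free reduced design. The timepoint F
#' statistic is the extra-sum-of-squares F (identical to the sequential
#' and Type-II F on this balanced design). Genes with zero residual
#' variance are flagged degenerate and their p is `NA`.
#'
#' @param expr Numeric vector (one gene) or gene x sample matrix, columns
#'   in the order of `design`.
#' @param design Sample sheet with `timepoint`, `bio_rep`, `tech_rep`.
#' @return A tibble with one row per gene: `gene_id`, `anova_F`,
#'   `anova_p`, `df1`, `df2`, `sigma2` (residual variance), `degenerate`.
#' @export
fit_gene_model <- function(expr, design) {
  if (is.null(dim(expr))) expr <- matrix(expr, nrow = 1)
  expr <- as.matrix(expr)
  if (!all(is.finite(expr))) stop("expression must be finite", call. = FALSE)
  mats <- de_design_matrices(design)
  if (ncol(expr) != nrow(mats$design))
    stop("expression columns must match the design rows", call. = FALSE)
  y <- t(expr)  # samples x genes

  rss <- function(qrx) {
    r <- qr.resid(qrx, y)
    colSums(r^2)
  }
  rss_full <- rss(mats$qr_full)
  rss_red <- rss(mats$qr_red)

  scale <- colMeans(y^2)
  degen <- rss_full <= pmax(scale, 1) * 1e-12
  sigma2 <- rss_full / mats$df_res
  f <- ((rss_red - rss_full) / mats$df_tp) / sigma2
  p <- stats::pf(f, mats$df_tp, mats$df_res, lower.tail = FALSE)
  f[degen] <- NA_real_
  p[degen] <- NA_real_

  tibble::tibble(
    gene_id = rownames(expr) %||% sprintf("gene%d", seq_len(nrow(expr))),
    anova_F = unname(f), anova_p = unname(p),
    df1 = mats$df_tp, df2 = mats$df_res,
    sigma2 = unname(sigma2), degenerate = unname(degen)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tukey pairwise timepoint contrasts
#'
#' For each timepoint pair (later minus earlier), computes the difference
#' of model-adjusted timepoint means and its studentized-range p-value
#' with family size equal to the number of timepoints and the residual
#' degrees of freedom of the full nested model (Tukey-Kramer standard
#' error for unbalanced groups). Degenerate genes (zero residual
#' variance) get `NA` p-values.
#'
#' @param expr Vector or gene x sample matrix, as [fit_gene_model()].
#' @param design Sample sheet.
#' @param fit Optional precomputed result of [fit_gene_model()] for the
#'   same `expr`/`design` (avoids refitting).
#' @return A tibble with one row per gene x pair: `gene_id`, `pair`
#'   (`"d3_d1"`, `"d7_d1"`, `"d7_d3"` for the default timepoints),
#'   `delta`, `tukey_p`.
#' @export
tukey_pairwise <- function(expr, design, fit = NULL) {
  if (is.null(dim(expr))) expr <- matrix(expr, nrow = 1)
  expr <- as.matrix(expr)
  if (is.null(fit)) fit <- fit_gene_model(expr, design)
  mats <- de_design_matrices(design)
  design <- mats$design
  tp <- droplevels(design$timepoint)
  k <- nlevels(tp)

  # adjusted timepoint means = per-timepoint means of full-model fitted
  # values (equal to raw group means on a balanced design)
  yhat <- qr.fitted(mats$qr_full, t(expr))  # samples x genes
  group_mean <- apply(yhat, 2, function(v) tapply(v, tp, mean))
  n_per <- as.vector(table(tp))

  pairs <- utils::combn(seq_len(k), 2)
  lev <- levels(tp)
  shorten <- function(l) sub("^day", "d", l)
  pair_label <- function(i, j) paste0(shorten(lev[j]), "_", shorten(lev[i]))
  out <- lapply(seq_len(ncol(pairs)), function(c_idx) {
    i <- pairs[1, c_idx]; j <- pairs[2, c_idx]
    delta <- group_mean[j, ] - group_mean[i, ]  # later minus earlier
    se <- sqrt(fit$sigma2 * (1 / n_per[i] + 1 / n_per[j]) / 2)
    q <- abs(delta) / se
    p <- stats::ptukey(q, nmeans = k, df = fit$df2, lower.tail = FALSE)
    p[fit$degenerate] <- NA_real_
    tibble::tibble(gene_id = fit$gene_id, pair = pair_label(i, j),
                   delta = as.numeric(delta), tukey_p = unname(p))
  })
  dplyr::bind_rows(out)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment. `NA` entries (degenerate
#' genes) propagate and are excluded from the family size `m`.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @return Adjusted p-values in the input order.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Call differentially expressed genes for one contrast
#'
#' @param results Tidy DE results (as from [run_rnaseq_de()]) with
#'   columns `gene_id`, `pair`, `delta`, `bh_p`.
#' @param alpha FDR threshold; a gene is called iff `bh_p < alpha`
#'   (strictly).
#' @param pair Which contrast to call, default `"d7_d1"`.
#' @return A list with character vectors `up` and `down`.
#' @export
call_de <- function(results, alpha = 0.05, pair = "d7_d1") {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)",
                                     call. = FALSE)
  r <- results[results$pair == pair & !is.na(results$bh_p), ]
  list(up = r$gene_id[r$bh_p < alpha & r$delta > 0],
       down = r$gene_id[r$bh_p < alpha & r$delta < 0])
}

#' Differential expression across the time course
#'
#' Full RNA-seq stage: RPM normalization (computed on the unfiltered
#' matrix), low-detection filtering on raw counts, per-gene nested
#' ANOVA, Tukey pairwise contrasts, and per-contrast BH adjustment
#' across genes. Modeling is on raw RPM by default; `scale = "log2"`
#' fits `log2(RPM + 1)` instead.
#'
#' @param counts Integer gene x sample matrix (or continuous matrix from
#'   the Gaussian/log-normal simulators).
#' @param design Sample sheet.
#' @param min_samples Detection filter threshold (see
#'   [filter_low_detection()]).
#' @param alpha FDR threshold used for the `direction` call.
#' @param scale `"rpm"` (default) or `"log2"` for `log2(RPM + 1)`.
#' @return A list with `results` (tibble: one row per gene x pair with
#'   `gene_id`, `pair`, `delta`, `anova_F`, `anova_p`, `tukey_p`, `bh_p`,
#'   `direction`), `removed` (filtered gene ids), `degenerate`
#'   (gene ids with undefined p), `rpm` (the filtered modeling matrix).
#' @export
run_rnaseq_de <- function(counts, design, min_samples = 5, alpha = 0.05,
                          scale = c("rpm", "log2")) {
  scale <- match.arg(scale)
  rpm <- normalize_rpm(counts)
  flt <- filter_low_detection(as.matrix(counts), min_samples)
  rpm <- rpm[rownames(flt$kept), , drop = FALSE]
  expr <- if (scale == "log2") log2(rpm + 1) else rpm

  fit <- fit_gene_model(expr, design)
  pw <- tukey_pairwise(expr, design, fit = fit)
  pw <- dplyr::left_join(
    pw, fit[, c("gene_id", "anova_F", "anova_p")], by = "gene_id")
  pw <- dplyr::group_by(pw, .data$pair)
  pw <- dplyr::mutate(pw, bh_p = adjust_bh(.data$tukey_p))
  pw <- dplyr::ungroup(pw)
  pw$direction <- ifelse(
    !is.na(pw$bh_p) & pw$bh_p < alpha & pw$delta != 0,
    ifelse(pw$delta > 0, "up", "down"), "none")

  list(results = pw[, c("gene_id", "pair", "delta", "anova_F", "anova_p",
                        "tukey_p", "bh_p", "direction")],
       removed = flt$removed,
       degenerate = fit$gene_id[fit$degenerate],
       rpm = expr)
}

#' Per-gene day7/day1 log2 fold-change from RPM means
#'
#' Convenience summary for cross-omics integration: the log2 ratio of
#' mean RPM at the later vs the earlier timepoint, with a pseudocount to
#' guard against zero means.
#'
#' @param rpm Gene x sample RPM matrix.
#' @param design Sample sheet.
#' @param later,earlier Timepoint labels, defaults `"day7"` / `"day1"`.
#' @param pseudocount Added to both means before the ratio.
#' @return A tibble with `gene_symbol`, `mean_earlier`, `mean_later`,
#'   `log2fc`.
#' @export
rna_log2fc <- function(rpm, design, later = "day7", earlier = "day1",
                       pseudocount = 1) {
  design <- check_design(design)
  m_e <- rowMeans(rpm[, design$timepoint == earlier, drop = FALSE])
  m_l <- rowMeans(rpm[, design$timepoint == later, drop = FALSE])
  tibble::tibble(gene_symbol = rownames(rpm),
                 mean_earlier = m_e, mean_later = m_l,
                 log2fc = log2((m_l + pseudocount) / (m_e + pseudocount)))
}
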