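#' Default TMT-6plex channel scheme
#'
#' Reporter channel to (timepoint, replicate) mapping used by the study:
#' 126/127/128 carry days 1/3/7 of replicate A and 129/130/131 the same
#' days of replicate B.
#'
#' @return A tibble with `channel`, `timepoint`, `replicate`.
#' @export
default_channel_scheme <- function() {
  tibble::tibble(
    channel = paste0("tmt", 126:131),
    timepoint = rep(c("day1", "day3", "day7"), 2),
    replicate = rep(c("A", "B"), each = 3)
  )
}

check_channel_scheme <- function(scheme) {
  need <- c("channel", "timepoint", "replicate")
  if (!all(need %in% names(scheme)))
    stop("channel scheme needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(scheme$channel) ||
      anyDuplicated(scheme[, c("timepoint", "replicate")]))
    stop("channel scheme must be a bijection channel <-> (timepoint, replicate)",
         call. = FALSE)
  if (!all(table(scheme$timepoint) == length(unique(scheme$replicate))))
    stop("every timepoint needs one channel per replicate", call. = FALSE)
  scheme
}

proteomics_comparisons <- function() {
  tibble::tibble(comparison = c("d3_d1", "d7_d1", "d7_d3"),
                 numerator = c("day3", "day7", "day7"),
                 denominator = c("day1", "day1", "day3"))
}

#' Remove contaminant proteins
#'
#' Drops records whose accession matches any pattern in the contaminant
#' list (regular expressions; typical entries match keratins, albumin or
#' a `CON_` prefix).
#'
#' @param records Long-form peptide table with an `accession` column.
#' @param contaminants Character vector of regex patterns; empty vector
#'   is the identity.
#' @return A list with `kept` and `removed` (tibbles).
#' @export
remove_contaminants <- function(records, contaminants = character()) {
  if (length(contaminants) == 0)
    return(list(kept = records, removed = records[0, ]))
  hit <- Reduce(`|`, lapply(contaminants, function(p)
    grepl(p, records$accession)))
  list(kept = records[!hit, , drop = FALSE],
       removed = records[hit, , drop = FALSE])
}

#' Peptide-level TMT ratios, median-normalized
#'
#' Forms within-replicate reporter ratios per peptide (day3/day1,
#' day7/day1, day7/day3 for each replicate) and divides every ratio
#' column by its median across peptides, so each column's median is
#' exactly 1. Peptides with a non-positive reporter value in any channel
#' are excluded and reported.
#'
#' @param records Long-form peptide table: `accession`, `gene_symbol`,
#'   `peptide_id`, one column per reporter channel.
#' @param scheme Channel scheme tibble, default
#'   [default_channel_scheme()].
#' @return A list with `ratios` (tibble: id columns plus
#'   `ratio_<comparison>_<replicate>`), `excluded` (tibble of dropped
#'   peptides with `reason`) and `medians` (the normalization factors).
#' @export
normalize_ratios <- function(records, scheme = default_channel_scheme()) {
  scheme <- check_channel_scheme(scheme)
  miss <- setdiff(scheme$channel, names(records))
  if (length(miss))
    stop("missing reporter columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  vals <- as.matrix(records[, scheme$channel])
  bad <- rowSums(!is.finite(vals) | vals <= 0) > 0
  excluded <- records[bad, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- "non-positive reporter value"
  rec <- records[!bad, , drop = FALSE]
  vals <- vals[!bad, , drop = FALSE]

  cmp <- proteomics_comparisons()
  reps <- sort(unique(scheme$replicate))
  ratios <- rec[, intersect(c("accession", "gene_symbol", "peptide_id"),
                            names(rec))]
  medians <- c()
  for (i in seq_len(nrow(cmp))) {
    for (r in reps) {
      num <- scheme$channel[scheme$timepoint == cmp$numerator[i] &
                              scheme$replicate == r]
      den <- scheme$channel[scheme$timepoint == cmp$denominator[i] &
                              scheme$replicate == r]
      col <- paste0("ratio_", cmp$comparison[i], "_", r)
      x <- vals[, num] / vals[, den]
      m <- stats::median(x)
      medians[col] <- m
      ratios[[col]] <- x / m
    }
  }
  list(ratios = ratios, excluded = excluded, medians = medians)
}

#' Summarize peptide ratios to protein profiles
#'
#' Per protein and (comparison, replicate): the protein-level ratio is
#' the median of peptide-level ratios and the reporter-ion variability is
#' the percent coefficient of variation (100 x SD / mean) of those
#' peptide ratios. Log2 ratios are averaged over replicates, and the
#' replicate discordance per comparison is the absolute difference of the
#' two replicates' log2 ratios.
#'
#' @param ratios Normalized peptide ratio table from
#'   [normalize_ratios()].
#' @return A tibble, one row per protein: `accession`, `gene_symbol`,
#'   `n_peptides`, `ratio_*`, `l2_*`, `cv_*` per (comparison, replicate),
#'   `mean_l2_*` and `disc_*` per comparison.
#' @export
summarize_protein <- function(ratios) {
  if (nrow(ratios) == 0) stop("no usable peptide ratios", call. = FALSE)
  ratio_cols <- grep("^ratio_", names(ratios), value = TRUE)
  g <- dplyr::group_by(ratios, .data$accession, .data$gene_symbol)
  prof <- dplyr::summarise(
    g,
    n_peptides = dplyr::n(),
    dplyr::across(dplyr::all_of(ratio_cols),
                  list(med = stats::median,
                       cv = function(x) 100 * stats::sd(x) / mean(x)),
                  .names = "{.col}__{.fn}"),
    .groups = "drop")

  out <- prof[, c("accession", "gene_symbol", "n_peptides")]
  cmp <- proteomics_comparisons()$comparison
  reps <- unique(sub("^ratio_d\\d_d\\d_", "",
                     grep("^ratio_", ratio_cols, value = TRUE)))
  for (cc in cmp) {
    for (r in reps) {
      med <- prof[[paste0("ratio_", cc, "_", r, "__med")]]
      cv <- prof[[paste0("ratio_", cc, "_", r, "__cv")]]
      cv[is.na(cv)] <- 0  # single peptide: no spread measurable
      out[[paste0("ratio_", cc, "_", r)]] <- med
      out[[paste0("l2_", cc, "_", r)]] <- log2(med)
      out[[paste0("cv_", cc, "_", r)]] <- cv
    }
    l2 <- sapply(reps, function(r) out[[paste0("l2_", cc, "_", r)]])
    if (is.null(dim(l2))) l2 <- matrix(l2, nrow = 1)
    out[[paste0("mean_l2_", cc)]] <- rowMeans(l2)
    out[[paste0("disc_", cc)]] <-
      if (length(reps) == 2) abs(l2[, 1] - l2[, 2]) else
        apply(l2, 1, function(v) stats::median(abs(outer(v, v, `-`)[lower.tri(diag(length(v)))])))
  }
  out
}

#' Quality-control exclusion cascade
#'
#' Excludes a protein if it has fewer than `min_peptides` peptides, OR a
#' reporter-ion variability (percent CV) strictly above `max_variability`
#' in at least one (comparison, replicate) ratio, OR a replicate log2
#' discordance strictly above `max_replicate_discordance` in at least one
#' comparison. All inequalities are strict, so a protein sitting exactly
#' on a threshold is kept. The reported `reason` is the first triggered
#' rule in the order above; the exclusion *set* does not depend on that
#' order.
#'
#' @param profiles Protein profiles from [summarize_protein()].
#' @param min_peptides,max_variability,max_replicate_discordance
#'   Thresholds; study defaults 3, 100 (percent), 0.4 (log2).
#' @return A list with `passing` (profiles with `qc_pass = TRUE`) and
#'   `excluded` (tibble with `accession`, `reason`).
#' @export
qc_filter <- function(profiles, min_peptides = 3, max_variability = 100,
                      max_replicate_discordance = 0.4) {
  if (min_peptides < 0 || max_variability < 0 || max_replicate_discordance < 0)
    stop("QC thresholds must be nonnegative", call. = FALSE)
  cv_cols <- grep("^cv_", names(profiles), value = TRUE)
  disc_cols <- grep("^disc_", names(profiles), value = TRUE)
  few <- profiles$n_peptides < min_peptides
  high_var <- apply(as.matrix(profiles[, cv_cols]) > max_variability, 1, any)
  discord <- apply(
    as.matrix(profiles[, disc_cols]) > max_replicate_discordance, 1, any)
  reason <- dplyr::case_when(
    few ~ "few_peptides",
    high_var ~ "high_variability",
    discord ~ "replicate_discordant",
    .default = NA_character_)
  excl <- !is.na(reason)
  passing <- profiles[!excl, , drop = FALSE]
  passing$qc_pass <- TRUE
  list(passing = passing,
       excluded = tibble::tibble(accession = profiles$accession[excl],
                                 gene_symbol = profiles$gene_symbol[excl],
                                 reason = reason[excl]))
}

#' Call regulated proteins
#'
#' A QC-passing protein is regulated when the absolute replicate-mean
#' log2 fold-change strictly exceeds `threshold` in at least one of the
#' three comparisons (d3/d1, d7/d1, d7/d3).
#'
#' @param profiles QC-passing profiles.
#' @param threshold Absolute log2 fold-change cutoff, study default 0.3.
#' @return `profiles` with a logical `regulated` column.
#' @export
call_regulated <- function(profiles, threshold = 0.3) {
  if (threshold < 0) stop("`threshold` must be >= 0", call. = FALSE)
  m <- as.matrix(profiles[, grep("^mean_l2_", names(profiles))])
  profiles$regulated <- apply(abs(m) > threshold, 1, any)
  profiles
}

#' Replicate Pearson correlation per comparison
#'
#' Correlation between replicate A and replicate B log2 ratios across
#' proteins, one value per comparison; the standard sanity check on TMT
#' replicate agreement.
#'
#' @param profiles Protein profiles with `l2_<comparison>_<replicate>`
#'   columns.
#' @return A tibble with `comparison`, `pearson_r`, `n`.
#' @export
replicate_correlation <- function(profiles) {
  if (nrow(profiles) < 3) stop("need at least 3 proteins", call. = FALSE)
  cmp <- proteomics_comparisons()$comparison
  out <- lapply(cmp, function(cc) {
    a <- profiles[[paste0("l2_", cc, "_A")]]
    b <- profiles[[paste0("l2_", cc, "_B")]]
    ok <- is.finite(a) & is.finite(b)
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
      stop("zero variance in replicate log2 ratios for ", cc, call. = FALSE)
    tibble::tibble(comparison = cc, pearson_r = stats::cor(a[ok], b[ok]),
                   n = sum(ok))
  })
  dplyr::bind_rows(out)
}

#' K-means clustering of regulated proteins into temporal archetypes
#'
#' Clusters the feature vectors `(mean log2 d3/d1, mean log2 d7/d1)` of
#' regulated proteins with `stats::kmeans` (Hartigan-Wong) over
#' `n_restarts` random starts under a fixed seed, keeping the
#' best-inertia solution. Cluster labels are then re-assigned
#' deterministically by sorting centroids on their d7/d1 coordinate in
#' decreasing order, so clusters 1-3 carry the upregulated and 4-6 the
#' downregulated trajectories (for k = 6).
#'
#' @param profiles Regulated protein profiles with `mean_l2_d3_d1` and
#'   `mean_l2_d7_d1` columns (e.g. from [call_regulated()], subset to
#'   `regulated`).
#' @param k Number of clusters, study default 6.
#' @param seed Integer seed.
#' @param n_restarts Random restarts, default 50.
#' @return A list with `clusters` (tibble: `accession`, `cluster`,
#'   `group` = `"up"`/`"down"` by centroid sign), `centers` (k x 2
#'   matrix, rows in final label order) and `tot_withinss`.
#' @export
kmeans_cluster <- function(profiles, k = 6, seed = 1L, n_restarts = 50) {
  x <- as.matrix(profiles[, c("mean_l2_d3_d1", "mean_l2_d7_d1")])
  if (nrow(x) < k)
    stop("fewer regulated proteins (", nrow(x), ") than clusters (", k, ")",
         call. = FALSE)
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = n_restarts, iter.max = 100)
  ord <- order(km$centers[, "mean_l2_d7_d1"], decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  centers <- km$centers[ord, , drop = FALSE]
  rownames(centers) <- seq_len(k)
  cluster <- relabel[km$cluster]
  list(
    clusters = tibble::tibble(
      accession = profiles$accession,
      cluster = cluster,
      group = ifelse(centers[cluster, "mean_l2_d7_d1"] > 0, "up", "down")),
    centers = centers,
    tot_withinss = km$tot.withinss
  )
}

#' Full proteomics stage
#'
#' Contaminant removal, ratio formation and median normalization,
#' protein-level summarization, QC cascade, regulation call and K-means
#' archetype clustering, in the study's order.
#'
#' @param records Long-form peptide table.
#' @param contaminants Regex patterns for contaminant accessions.
#' @param scheme Channel scheme.
#' @param min_peptides,max_variability,max_replicate_discordance,threshold
#'   QC and regulation thresholds (study defaults).
#' @param k,seed,n_restarts Clustering controls.
#' @return A list with `profiles` (all summarized proteins, with
#'   `qc_pass`, `regulated`, `cluster` columns), `excluded` (QC
#'   exclusions with reasons), `contaminants_removed`,
#'   `replicate_correlation`, `clustering` (the [kmeans_cluster()]
#'   result, or `NULL` if too few regulated proteins).
#' @export
run_proteomics <- function(records, contaminants = c("^CON_"),
                           scheme = default_channel_scheme(),
                           min_peptides = 3, max_variability = 100,
                           max_replicate_discordance = 0.4, threshold = 0.3,
                           k = 6, seed = 1L, n_restarts = 50) {
  decon <- remove_contaminants(records, contaminants)
  norm <- normalize_ratios(decon$kept, scheme)
  prof <- summarize_protein(norm$ratios)
  qc <- qc_filter(prof, min_peptides, max_variability,
                  max_replicate_discordance)
  passing <- call_regulated(qc$passing, threshold)
  rep_cor <- replicate_correlation(passing)

  reg <- passing[passing$regulated, , drop = FALSE]
  clustering <- if (nrow(reg) >= k)
    kmeans_cluster(reg, k = k, seed = seed, n_restarts = n_restarts)
  else NULL

  prof$qc_pass <- !(prof$accession %in% qc$excluded$accession)
  prof$regulated <- prof$accession %in% reg$accession
  prof$cluster <- NA_integer_
  if (!is.null(clustering))
    prof$cluster[match(clustering$clusters$accession, prof$accession)] <-
      clustering$clusters$cluster

  list(profiles = prof, excluded = qc$excluded,
       contaminants_removed = unique(decon$removed$accession),
       peptides_excluded = norm$excluded,
       replicate_correlation = rep_cor, clustering = clustering)
}
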