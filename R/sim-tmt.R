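#' Simulate a TMT-6plex peptide-level protein quantification table
#'
#' Builds a long-form reporter table (one row per peptide, six reporter
#' channels following the day1/day3/day7 x replicate A/B scheme of
#' [default_channel_scheme()]) with planted ground truth. A deterministic
#' number of proteins (`round(rate * n_proteins)` per class) is planted as
#' QC violators: contaminants (keratin/albumin-style accessions), proteins
#' with fewer than three peptides, proteins with inflated peptide-level
#' reporter variability, and proteins whose replicates disagree by more
#' than 0.4 log2 units in one ratio. Among clean proteins, a configurable
#' fraction is planted as regulated with one of six temporal archetype
#' profiles; the remainder are flat.
#'
#' Peptide noise is log-normal and calibrated so that the percent CV of
#' peptide-level *ratios* matches `peptide_cv_percent`.
#'
#' @param config A [sim_config()].
#' @return A list with `records` (tibble: `accession`, `gene_symbol`,
#'   `peptide_id`, `tmt126` .. `tmt131`) and `truth` (tibble: `accession`,
#'   `gene_symbol`, `qc_violation_label`, `planted_regulated`,
#'   `archetype`, `l2fc_d3_d1`, `l2fc_d7_d1`).
#' @export
simulate_tmt <- function(config) {
  validate_sim_config(config)
  n <- config$n_proteins
  set.seed(config$seed + 1L)

  rates <- config$qc_violation_rates
  n_con <- round(rates[["contaminant"]] * n)
  n_few <- round(rates[["few_peptides"]] * n)
  n_hv <- round(rates[["high_variability"]] * n)
  n_rd <- round(rates[["replicate_discordant"]] * n)

  label <- rep("none", n)
  idx <- sample.int(n)  # random identity, deterministic counts
  label[idx[seq_len(n_con)]] <- "contaminant"
  off <- n_con
  label[idx[off + seq_len(n_few)]] <- "few_peptides"
  off <- off + n_few
  label[idx[off + seq_len(n_hv)]] <- "high_variability"
  off <- off + n_hv
  label[idx[off + seq_len(n_rd)]] <- "replicate_discordant"

  accession <- sprintf("PROT%05d", seq_len(n))
  gene_symbol <- sprintf("GENE%05d", seq_len(n))
  is_con <- label == "contaminant"
  if (any(is_con)) {
    accession[is_con] <- sprintf("CON_KRT%03d", seq_len(sum(is_con)))
    gene_symbol[is_con] <- sprintf("KRT%d", seq_len(sum(is_con)))
  }

  # planted regulation among clean proteins only
  clean <- which(label == "none")
  n_reg <- round(config$regulated_fraction * length(clean))
  reg_idx <- clean[sample.int(length(clean), n_reg)]
  archetype <- rep(NA_integer_, n)
  archetype[reg_idx] <- sample(rep_len(1:6, n_reg))
  l3 <- ifelse(is.na(archetype), 0, config$archetype_profiles[archetype, 1])
  l7 <- ifelse(is.na(archetype), 0, config$archetype_profiles[archetype, 2])

  # per-protein per-(timepoint, replicate) log2 offsets; replicate B of a
  # discordant protein gets one timepoint shifted by +/- 0.8 log2 units
  eps <- array(stats::rnorm(n * 3 * 2, 0, config$rep_log2_sd),
               dim = c(n, 3, 2),
               dimnames = list(NULL, c("day1", "day3", "day7"), c("A", "B")))
  rd <- which(label == "replicate_discordant")
  if (length(rd)) {
    shift_tp <- sample(c("day3", "day7"), length(rd), replace = TRUE)
    shift_sgn <- sample(c(-1, 1), length(rd), replace = TRUE)
    for (i in seq_along(rd))
      eps[rd[i], shift_tp[i], "B"] <- eps[rd[i], shift_tp[i], "B"] +
        0.8 * shift_sgn[i]
  }

  n_pep <- 3L + stats::rpois(n, config$peptides_mean)
  n_pep[label == "few_peptides"] <- sample(1:2, sum(label == "few_peptides"),
                                           replace = TRUE)

  cv <- rep(config$peptide_cv_percent, n)
  cv[label == "high_variability"] <- max(300, 3 * config$peptide_cv_percent)
  # channel-level log SD so that the two-channel ratio has the stated CV
  sd_ch <- sqrt(log1p((cv / 100)^2)) / sqrt(2)

  base_l2 <- stats::runif(n, 14, 20)
  scheme <- default_channel_scheme()
  # per-protein log2 channel abundance, ratios cancel the baseline
  prof <- cbind(day1 = 0, day3 = l3, day7 = l7)

  rows <- rep.int(seq_len(n), n_pep)
  n_rows <- length(rows)
  pep_eff <- stats::rlnorm(n_rows, 0, 0.5)
  rec <- tibble::tibble(
    accession = accession[rows],
    gene_symbol = gene_symbol[rows],
    peptide_id = sprintf("%s_pep%02d", accession[rows],
                         unlist(lapply(n_pep, seq_len)))
  )
  for (j in seq_len(nrow(scheme))) {
    ch <- scheme$channel[j]
    tp <- scheme$timepoint[j]
    rp <- scheme$replicate[j]
    mu_l2 <- base_l2[rows] + prof[cbind(rows, match(tp, colnames(prof)))] +
      eps[cbind(rows, match(tp, dimnames(eps)[[2]]),
                match(rp, dimnames(eps)[[3]]))]
    rec[[ch]] <- 2^mu_l2 * pep_eff *
      exp(stats::rnorm(n_rows, 0, sd_ch[rows]))
  }

  truth <- tibble::tibble(
    accession = accession, gene_symbol = gene_symbol,
    qc_violation_label = label,
    planted_regulated = !is.na(archetype),
    archetype = archetype,
    l2fc_d3_d1 = l3, l2fc_d7_d1 = l7
  )
  list(records = rec, truth = truth)
}

#' Simulate protein-level temporal profiles with planted archetypes
#'
#' Skips the peptide layer and draws protein-level feature vectors
#' `(mean log2 d3/d1, mean log2 d7/d1)` directly around the six archetype
#' centroids with isotropic Gaussian noise. Intended for clustering
#' calibration and power studies where the noise level on the final log2
#' ratios must be controlled exactly.
#'
#' @param n_proteins Number of regulated proteins to draw (balanced over
#'   the six archetypes up to rounding).
#' @param archetypes 6 x 2 matrix of centroids, as [default_archetypes()].
#' @param noise_sd Gaussian SD added to each log2 ratio coordinate.
#' @param seed Integer seed.
#' @return A tibble with `accession`, `mean_l2_d3_d1`, `mean_l2_d7_d1`,
#'   `archetype` (the planted label).
#' @export
simulate_profiles <- function(n_proteins, archetypes = default_archetypes(),
                              noise_sd = 0.1, seed = 1L) {
  stopifnot(n_proteins >= 6, noise_sd >= 0)
  set.seed(seed)
  lab <- sample(rep_len(seq_len(nrow(archetypes)), n_proteins))
  tibble::tibble(
    accession = sprintf("PROT%05d", seq_len(n_proteins)),
    mean_l2_d3_d1 = archetypes[lab, 1] + stats::rnorm(n_proteins, 0, noise_sd),
    mean_l2_d7_d1 = archetypes[lab, 2] + stats::rnorm(n_proteins, 0, noise_sd),
    archetype = lab
  )
}
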