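#' Simulate a gene x sample count matrix with planted DE truth
#'
#' Draws expression for every (gene, sample) pair from a log-linear model:
#' log2 mean = baseline + timepoint effect (nonzero only for planted DE
#' genes) + biological-replicate effect + technical-replicate effect,
#' scaled by a per-sample library-size factor. Under the default
#' `family = "nb"` counts are negative binomial with variance
#' `mu + dispersion * mu^2`; `"gaussian"` and `"lognormal"` return
#' continuous matrices suited to calibration and power studies of the
#' downstream linear model.
#'
#' Exactly `round(n_genes * de_fraction)` genes are flagged DE; half are
#' up- and half downregulated at day 7 vs day 1 by `effect_log2fc`, with
#' a monotone day1 -> day3 -> day7 trajectory (the day-3 effect is a
#' random fraction in \[0.25, 0.75\] of the day-7 effect).
#'
#' @param config A [sim_config()].
#' @param design A sample sheet as from [default_design()].
#' @return A list with elements `counts` (gene x sample matrix, integer
#'   for the NB family), `truth` (tibble: `gene_id`, `is_de`,
#'   `direction`, `l2fc_d3_d1`, `l2fc_d7_d1`, `l2fc_d7_d3`) and `design`.
#' @export
simulate_counts <- function(config, design = default_design()) {
  validate_sim_config(config)
  design <- check_design(design)
  n_g <- config$n_genes
  n_s <- nrow(design)
  set.seed(config$seed)

  gene_id <- sprintf("GENE%05d", seq_len(n_g))
  base_l2 <- stats::runif(n_g, 3, 9)

  n_de <- round(n_g * config$de_fraction)
  de_idx <- sort(sample.int(n_g, n_de))
  is_de <- seq_len(n_g) %in% de_idx
  direction <- rep("none", n_g)
  l7 <- numeric(n_g)
  l3 <- numeric(n_g)
  if (n_de > 0) {
    n_up <- ceiling(n_de / 2)
    up_idx <- de_idx[sample.int(n_de, n_up)]
    sgn <- ifelse(seq_len(n_g) %in% up_idx, 1, -1) * is_de
    l7 <- sgn * config$effect_log2fc
    l3 <- l7 * stats::runif(n_g, 0.25, 0.75)
    direction[is_de] <- ifelse(sgn[is_de] > 0, "up", "down")
  }

  tp_effect <- matrix(0, n_g, n_s)
  tp <- as.character(design$timepoint)
  tp_effect[, tp == "day3"] <- l3
  tp_effect[, tp == "day7"] <- l7

  bio_lev <- levels(design$bio_rep)
  bio_eff <- matrix(stats::rnorm(n_g * length(bio_lev), 0, config$sigma_bio),
                    n_g, length(bio_lev), dimnames = list(NULL, bio_lev))
  cell <- interaction(design$bio_rep, design$tech_rep, drop = TRUE)
  tech_eff <- matrix(stats::rnorm(n_g * nlevels(cell), 0, config$sigma_tech),
                     n_g, nlevels(cell), dimnames = list(NULL, levels(cell)))

  log2_mu <- base_l2 + tp_effect +
    bio_eff[, as.character(design$bio_rep), drop = FALSE] +
    tech_eff[, as.character(cell), drop = FALSE]

  lib_fac <- if (config$lib_size_cv > 0) {
    sdlog <- sqrt(log1p(config$lib_size_cv^2))
    stats::rlnorm(n_s, -sdlog^2 / 2, sdlog)
  } else rep(1, n_s)

  # scale baselines so the expected column total matches lib_size_mean
  mu <- 2^log2_mu
  mu <- mu * (config$lib_size_mean / sum(2^base_l2))
  mu <- sweep(mu, 2, lib_fac, `*`)

  counts <- switch(config$family,
    nb = {
      if (config$nb_dispersion < 1e-8) {
        matrix(stats::rpois(n_g * n_s, as.vector(mu)), n_g, n_s)
      } else {
        matrix(stats::rnbinom(n_g * n_s, mu = as.vector(mu),
                              size = 1 / config$nb_dispersion), n_g, n_s)
      }
    },
    gaussian = {
      sd_g <- config$sigma_resid * rowMeans(mu)
      mu + matrix(stats::rnorm(n_g * n_s, 0, rep(sd_g, n_s)), n_g, n_s)
    },
    lognormal = {
      2^(log2(mu) + matrix(stats::rnorm(n_g * n_s, 0, config$sigma_resid),
                           n_g, n_s))
    }
  )
  dimnames(counts) <- list(gene_id, design$sample_id)

  truth <- tibble::tibble(
    gene_id = gene_id, is_de = is_de, direction = direction,
    l2fc_d3_d1 = l3, l2fc_d7_d1 = l7, l2fc_d7_d3 = l7 - l3
  )
  list(counts = counts, truth = truth, design = design)
}
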