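#' Default six-archetype temporal profiles
#'
#' Each archetype is a pair of planted log2 fold-changes
#' `(day3/day1, day7/day1)` describing one of six temporal trajectories of
#' regulated proteins: three upregulated shapes (slight steady rise, late
#' rise after day 3, early rise then plateau) and their three mirrored
#' downregulated counterparts. These are the default planted centroids for
#' [simulate_tmt()] and [simulate_profiles()].
#'
#' @return A 6 x 2 numeric matrix with columns `l2fc_d3_d1`, `l2fc_d7_d1`.
#' @export
default_archetypes <- function() {
  m <- rbind(
    c(0.20, 0.50),   # slight steady increase
    c(0.10, 1.20),   # late rise (day 3 -> day 7)
    c(0.90, 1.00),   # early rise then plateau
    c(-0.20, -0.50),
    c(-0.10, -1.20),
    c(-0.90, -1.00)
  )
  dimnames(m) <- list(paste0("archetype", 1:6), c("l2fc_d3_d1", "l2fc_d7_d1"))
  m
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators into a validated
#' list. Defaults describe a study with three timepoints (day 1, 3, 7),
#' two biological replicates each with two nested technical replicates,
#' negative-binomial counts, and a TMT-6plex protein layer.
#'
#' @param n_genes Number of genes in the RNA layer.
#' @param n_proteins Number of proteins in the TMT layer.
#' @param de_fraction Fraction of genes planted as differentially
#'   expressed; exactly `round(n_genes * de_fraction)` genes are flagged.
#' @param effect_log2fc Planted absolute log2 fold-change at day 7 vs
#'   day 1 for DE genes (half up, half down, monotone over time).
#' @param sigma_bio,sigma_tech SD (log2 scale) of per-gene biological and
#'   technical replicate effects.
#' @param sigma_resid Residual noise scale: for `family = "gaussian"` the
#'   per-gene coefficient of variation of additive noise; for
#'   `family = "lognormal"` the residual SD in log2 units.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); values below 1e-8 fall back to Poisson.
#' @param lib_size_mean Expected library size (column total) per sample.
#' @param lib_size_cv Coefficient of variation of library size factors
#'   across samples (0 = equal libraries).
#' @param family Count noise family: `"nb"` (integer counts, default),
#'   `"gaussian"` (continuous, additive within-gene homoskedastic noise,
#'   intended for calibration studies) or `"lognormal"` (continuous,
#'   multiplicative log-scale noise).
#' @param archetype_profiles 6 x 2 matrix of planted (d3/d1, d7/d1) log2
#'   fold-changes; three rows must have positive and three negative
#'   d7/d1 components.
#' @param regulated_fraction Fraction of clean (QC-passing) proteins
#'   planted with a non-flat archetype profile.
#' @param peptide_cv_percent Percent CV of peptide-level reporter noise
#'   for clean proteins.
#' @param peptides_mean Mean extra peptides per protein beyond the
#'   3-peptide QC floor (clean proteins get `3 + rpois(peptides_mean)`).
#' @param rep_log2_sd SD (log2) of per-protein replicate offsets, the
#'   source of replicate discordance in clean proteins.
#' @param qc_violation_rates Named fractions of proteins planted as QC
#'   violators: `few_peptides`, `high_variability`, `replicate_discordant`,
#'   `contaminant`. Counts are deterministic (`round(rate * n_proteins)`).
#' @param n_terms Number of GO-style terms to simulate.
#' @param term_size_range Integer range of genes per term.
#' @param n_enriched_terms Number of terms planted as enriched in the DE
#'   gene set.
#' @param enriched_odds_ratio Odds ratio by which enriched terms
#'   over-sample DE genes (1 = no enrichment planted).
#' @param rho_rna_protein True correlation between RNA and protein day7/day1
#'   log2 fold-changes in the linked layer.
#' @param unshared_fraction Fraction of symbols present in only one omics
#'   layer.
#' @param seed Integer seed; every generator call is deterministic given
#'   the config seed.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_proteins = 600,
                       de_fraction = 0.1,
                       effect_log2fc = 2,
                       sigma_bio = 0.1,
                       sigma_tech = 0.05,
                       sigma_resid = 0.25,
                       nb_dispersion = 0.05,
                       lib_size_mean = 2e6,
                       lib_size_cv = 0.1,
                       family = c("nb", "gaussian", "lognormal"),
                       archetype_profiles = default_archetypes(),
                       regulated_fraction = 0.4,
                       peptide_cv_percent = 20,
                       peptides_mean = 5,
                       rep_log2_sd = 0.05,
                       qc_violation_rates = c(few_peptides = 0.05,
                                              high_variability = 0.05,
                                              replicate_discordant = 0.05,
                                              contaminant = 0.05),
                       n_terms = 50,
                       term_size_range = c(10, 40),
                       n_enriched_terms = 3,
                       enriched_odds_ratio = 10,
                       rho_rna_protein = 0.51,
                       unshared_fraction = 0.1,
                       seed = 1L) {
  family <- match.arg(family)
  cfg <- list(
    n_genes = as.integer(n_genes), n_proteins = as.integer(n_proteins),
    de_fraction = de_fraction, effect_log2fc = effect_log2fc,
    sigma_bio = sigma_bio, sigma_tech = sigma_tech,
    sigma_resid = sigma_resid, nb_dispersion = nb_dispersion,
    lib_size_mean = as.integer(lib_size_mean), lib_size_cv = lib_size_cv,
    family = family, archetype_profiles = archetype_profiles,
    regulated_fraction = regulated_fraction,
    peptide_cv_percent = peptide_cv_percent,
    peptides_mean = peptides_mean, rep_log2_sd = rep_log2_sd,
    qc_violation_rates = qc_violation_rates,
    n_terms = as.integer(n_terms), term_size_range = term_size_range,
    n_enriched_terms = as.integer(n_enriched_terms),
    enriched_odds_ratio = enriched_odds_ratio,
    rho_rna_protein = rho_rna_protein,
    unshared_fraction = unshared_fraction,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes > 0, cfg$n_proteins > 0)
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1)
    stop("`de_fraction` must lie in [0, 1]", call. = FALSE)
  if (cfg$effect_log2fc < 0) stop("`effect_log2fc` must be >= 0", call. = FALSE)
  if (cfg$sigma_bio < 0 || cfg$sigma_tech < 0 || cfg$sigma_resid < 0)
    stop("replicate/residual SDs must be >= 0", call. = FALSE)
  if (cfg$nb_dispersion < 0) stop("`nb_dispersion` must be >= 0", call. = FALSE)
  if (cfg$peptide_cv_percent < 0)
    stop("`peptide_cv_percent` must be >= 0", call. = FALSE)
  if (abs(cfg$rho_rna_protein) > 1)
    stop("`rho_rna_protein` must lie in [-1, 1]", call. = FALSE)
  arch <- cfg$archetype_profiles
  if (!is.matrix(arch) || nrow(arch) != 6 || ncol(arch) != 2)
    stop("`archetype_profiles` must be a 6 x 2 matrix", call. = FALSE)
  if (sum(arch[, 2] > 0) != 3 || sum(arch[, 2] < 0) != 3)
    stop("three archetypes must have positive and three negative d7/d1 components",
         call. = FALSE)
  rates <- cfg$qc_violation_rates
  needed <- c("few_peptides", "high_variability", "replicate_discordant",
              "contaminant")
  if (!all(needed %in% names(rates)) || any(rates < 0) || sum(rates) > 1)
    stop("`qc_violation_rates` must name all four violation classes, be >= 0 ",
         "and sum to at most 1", call. = FALSE)
  invisible(cfg)
}

#' Default 12-sample study design
#'
#' Three timepoints (day1, day3, day7) x two biological replicates (A, B)
#' x two technical replicates (1, 2) nested within each biological
#' replicate.
#'
#' @return A tibble with columns `sample_id`, `timepoint`, `bio_rep`,
#'   `tech_rep` (all factors except `sample_id`).
#' @export
default_design <- function() {
  d <- expand.grid(tech_rep = c("1", "2"), bio_rep = c("A", "B"),
                   timepoint = c("day1", "day3", "day7"),
                   stringsAsFactors = FALSE)
  tibble::tibble(
    sample_id = sprintf("%s_%s%s", d$timepoint, d$bio_rep, d$tech_rep),
    timepoint = factor(d$timepoint, levels = c("day1", "day3", "day7")),
    bio_rep = factor(d$bio_rep),
    tech_rep = factor(d$tech_rep)
  )
}

check_design <- function(design) {
  need <- c("sample_id", "timepoint", "bio_rep", "tech_rep")
  if (!all(need %in% names(design)))
    stop("design must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  design$timepoint <- as.factor(design$timepoint)
  design$bio_rep <- as.factor(design$bio_rep)
  design$tech_rep <- as.factor(design$tech_rep)
  if (anyDuplicated(design[, c("timepoint", "bio_rep", "tech_rep")]))
    stop("each (timepoint, bio_rep, tech_rep) combination may appear at most once",
         call. = FALSE)
  if (nlevels(droplevels(design$timepoint)) < 2)
    stop("design needs at least 2 timepoints", call. = FALSE)
  design
}
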