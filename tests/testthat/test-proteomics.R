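test_that("contaminant removal matches patterns and logs them", {
  rec <- tibble::tibble(accession = c("P1", "CON_KRT001", "P2", "ALB_HUMAN"),
                        gene_symbol = c("A", "KRT1", "B", "ALB"))
  out <- remove_contaminants(rec, c("^CON_", "^ALB"))
  expect_setequal(out$kept$accession, c("P1", "P2"))
  expect_setequal(out$removed$accession, c("CON_KRT001", "ALB_HUMAN"))
  expect_identical(remove_contaminants(rec, character())$kept, rec)
})

test_that("the fixture's planted contaminants are exactly the removed set", {
  fx <- load_fixture()
  out <- remove_contaminants(fx$proteins, fx$contaminants)
  planted <- fx$protein_truth$accession[
    fx$protein_truth$qc_violation_label == "contaminant"]
  expect_length(planted, 3)
  expect_setequal(unique(out$removed$accession), planted)
  expect_equal(dplyr::n_distinct(out$kept$accession), 57)
})

test_that("ratio columns are median-normalized to exactly 1 and idempotently", {
  # three peptides of one protein with channel values giving ratio 1, 2, 3
  # for day3/day1 replicate A
  recs <- make_records("P1", list(
    c(1, 1, 1, 1, 1, 1),
    c(1, 2, 3, 1, 2, 3),
    c(1, 3, 9, 1, 3, 9)))
  norm <- normalize_ratios(recs)
  # raw d3/d1 A ratios are (1, 2, 3): median 2 -> (0.5, 1, 1.5)
  expect_equal(norm$ratios$ratio_d3_d1_A, c(0.5, 1, 1.5))
  r_cols <- grep("^ratio_", names(norm$ratios), value = TRUE)
  for (cc in r_cols)
    expect_equal(stats::median(norm$ratios[[cc]]), 1, tolerance = 1e-12)
  # idempotence: medians of a normalized table are 1, renormalizing is a no-op
  rec2 <- recs
  # reconstruct records whose ratios are already the normalized ones is
  # equivalent to renormalizing the ratio table directly
  renorm <- norm$ratios
  for (cc in r_cols) renorm[[cc]] <- renorm[[cc]] / stats::median(renorm[[cc]])
  expect_equal(renorm, norm$ratios)
  # non-positive reporters are excluded with a reason
  bad <- make_records("P2", list(c(0, 1, 1, 1, 1, 1)))
  both <- rbind(recs, bad)
  norm2 <- normalize_ratios(both)
  expect_equal(norm2$excluded$accession, "P2")
  expect_match(norm2$excluded$reason, "non-positive")
})

test_that("protein summarization uses peptide medians and percent CV", {
  # one protein, three peptides; d3/d1 replicate A peptide ratios (1, 1, 4)
  recs <- make_records("P1", list(
    c(1, 1, 1, 1, 1, 1),
    c(1, 1, 1, 1, 1, 1),
    c(1, 4, 4, 1, 4, 4)))
  ratios <- normalize_ratios(recs)$ratios
  # place the raw (1, 1, 4) peptide ratios in one column directly
  ratios$ratio_d3_d1_A <- c(1, 1, 4)
  prof <- summarize_protein(ratios)
  expect_equal(prof$n_peptides, 3)
  expect_equal(prof$ratio_d3_d1_A, 1)              # median
  expect_equal(prof$cv_d3_d1_A, 100 * sd(c(1, 1, 4)) / 2, tolerance = 1e-9)
  expect_equal(round(prof$cv_d3_d1_A, 1), 86.6)
})

test_that("replicate means and discordance follow from the log2 ratios", {
  prof <- make_profile(mean_l2 = c(d3_d1 = 0.3, d7_d1 = 0.3, d7_d3 = 0),
                       disc = c(d3_d1 = 0.2, d7_d1 = 0, d7_d3 = 0))
  # replicates at log2 0.4 and 0.2 -> mean 0.3, discordance 0.2
  expect_equal(prof$l2_d3_d1_A, 0.4)
  expect_equal(prof$l2_d3_d1_B, 0.2)
  expect_equal(prof$mean_l2_d3_d1, 0.3)
  expect_equal(prof$disc_d3_d1, 0.2)
})

test_that("log2 ratio identity d7/d3 = d7/d1 - d3/d1 holds for unit-median data", {
  # noise-free channels: column medians are exactly 1, so normalization
  # is the identity and the ratio identity is exact
  mk <- function(l3, l7) 2^c(0, l3, l7, 0, l3, l7)
  recs <- rbind(make_records("P1", list(mk(0.4, 1.0))),
                make_records("P2", list(mk(-0.4, -1.0))),
                make_records("P3", list(mk(0, 0))))
  prof <- summarize_protein(normalize_ratios(recs)$ratios)
  expect_equal(prof$mean_l2_d7_d3,
               prof$mean_l2_d7_d1 - prof$mean_l2_d3_d1, tolerance = 1e-9)
})

test_that("QC cascade enforces strict thresholds with first-reason reporting", {
  boundary <- dplyr::bind_rows(
    make_profile("pep2", n_peptides = 2),
    make_profile("pep3", n_peptides = 3),
    make_profile("cv120", cv = 120),
    make_profile("cv100", cv = 100),
    make_profile("disc05", disc = c(d3_d1 = 0, d7_d1 = 0.5, d7_d3 = 0)),
    make_profile("disc04", disc = c(d3_d1 = 0, d7_d1 = 0.4, d7_d3 = 0)),
    make_profile("clean"))
  qc <- qc_filter(boundary)
  expect_setequal(qc$excluded$accession, c("pep2", "cv120", "disc05"))
  expect_equal(qc$excluded$reason[qc$excluded$accession == "pep2"],
               "few_peptides")
  expect_equal(qc$excluded$reason[qc$excluded$accession == "cv120"],
               "high_variability")
  expect_equal(qc$excluded$reason[qc$excluded$accession == "disc05"],
               "replicate_discordant")
  expect_setequal(qc$passing$accession, c("pep3", "cv100", "disc04", "clean"))
  expect_error(qc_filter(boundary, min_peptides = -1), "nonnegative")
})

test_that("QC exclusion set is order-independent", {
  # overlapping violations: protein failing all three rules
  multi <- make_profile("multi", n_peptides = 1, cv = 150,
                        disc = c(d3_d1 = 1, d7_d1 = 0, d7_d3 = 1))
  prof <- dplyr::bind_rows(multi, make_profile("clean"))
  qc <- qc_filter(prof)
  # brute force: union of the three independent rules
  brute <- unique(c(
    prof$accession[prof$n_peptides < 3],
    prof$accession[apply(as.matrix(prof[, grep("^cv_", names(prof))]) > 100,
                         1, any)],
    prof$accession[apply(as.matrix(prof[, grep("^disc_", names(prof))]) > 0.4,
                         1, any)]))
  expect_setequal(qc$excluded$accession, brute)
})

test_that("regulation call uses a strict 0.3 threshold on any comparison", {
  prof <- dplyr::bind_rows(
    make_profile("reg", mean_l2 = c(d3_d1 = 0.35, d7_d1 = 0.1, d7_d3 = -0.25)),
    make_profile("flat", mean_l2 = c(d3_d1 = 0.3, d7_d1 = -0.3, d7_d3 = 0)),
    make_profile("neg", mean_l2 = c(d3_d1 = 0, d7_d1 = -0.31, d7_d3 = -0.31)))
  out <- call_regulated(prof)
  expect_identical(out$regulated, c(TRUE, FALSE, TRUE))
  expect_error(call_regulated(prof, threshold = -0.1), ">= 0")
})

test_that("replicate correlation is 1 for identical replicates and attenuates with noise", {
  set.seed(55)
  n <- 2000
  truth <- rnorm(n, 0, 0.5)
  prof <- tibble::tibble(accession = sprintf("P%04d", 1:n),
                         gene_symbol = sprintf("P%04d", 1:n))
  for (cc in c("d3_d1", "d7_d1", "d7_d3")) {
    prof[[paste0("l2_", cc, "_A")]] <- truth
    prof[[paste0("l2_", cc, "_B")]] <- truth
  }
  expect_equal(replicate_correlation(prof)$pearson_r, rep(1, 3))
  # independent replicate noise SD 0.1 -> expected r = 0.25 / 0.26
  prof$l2_d7_d1_A <- truth + rnorm(n, 0, 0.1)
  prof$l2_d7_d1_B <- truth + rnorm(n, 0, 0.1)
  r <- replicate_correlation(prof)$pearson_r[2]
  r_exp <- 0.5^2 / (0.5^2 + 0.1^2)
  se_z <- 1 / sqrt(n - 3)
  expect_lt(abs(atanh(r) - atanh(r_exp)), 3 * se_z)
  # pure noise decorrelates
  prof$l2_d3_d1_A <- rnorm(n)
  prof$l2_d3_d1_B <- rnorm(n)
  expect_lt(abs(replicate_correlation(prof)$pearson_r[1]), 3 / sqrt(n))
})

test_that("k-means separates point clouds exactly and deterministically", {
  set.seed(61)
  prof <- tibble::tibble(
    accession = sprintf("P%03d", 1:40),
    mean_l2_d3_d1 = c(rnorm(20, 5, 0.01), rnorm(20, -5, 0.01)),
    mean_l2_d7_d1 = c(rnorm(20, 5, 0.01), rnorm(20, -5, 0.01)))
  km <- kmeans_cluster(prof, k = 2, seed = 9)
  expect_equal(km$clusters$cluster, rep(c(1, 2), each = 20))
  expect_lt(km$tot_withinss, 0.1)
  km2 <- kmeans_cluster(prof, k = 2, seed = 9)
  expect_identical(km$clusters, km2$clusters)
  expect_error(kmeans_cluster(prof[1:3, ], k = 6), "fewer regulated")
})

test_that("cluster relabeling is a deterministic function of the centroids", {
  prof <- simulate_profiles(120, noise_sd = 0.05, seed = 13)
  km <- kmeans_cluster(prof, k = 6, seed = 2)
  # labels 1..3 have positive, 4..6 negative d7/d1 centroids, in
  # decreasing order
  expect_true(all(diff(km$centers[, "mean_l2_d7_d1"]) < 0))
  expect_true(all(km$centers[1:3, "mean_l2_d7_d1"] > 0))
  expect_true(all(km$centers[4:6, "mean_l2_d7_d1"] < 0))
  expect_setequal(unique(km$clusters$group[km$clusters$cluster <= 3]), "up")
  # permuting input rows permutes labels consistently
  perm <- sample(nrow(prof))
  km_p <- kmeans_cluster(prof[perm, ], k = 6, seed = 2)
  m <- match(prof$accession, km_p$clusters$accession)
  expect_equal(km_p$clusters$cluster[m], km$clusters$cluster)
})

test_that("QC cascade on the packaged fixture reproduces the planted truth", {
  fx <- load_fixture()
  res <- run_proteomics(fx$proteins, contaminants = fx$contaminants,
                        seed = 1)
  truth <- fx$protein_truth
  viol <- truth[!truth$qc_violation_label %in% c("none", "contaminant"), ]
  expect_setequal(res$excluded$accession, viol$accession)
  m <- merge(res$excluded, viol, by = "accession")
  expect_equal(m$reason, m$qc_violation_label)
  # per-reason counts
  expect_equal(as.vector(table(res$excluded$reason)),
               as.vector(table(viol$qc_violation_label)))
  # regulated = QC pass and planted archetype
  reg_true <- truth$accession[truth$planted_regulated &
                                truth$qc_violation_label == "none"]
  expect_setequal(res$profiles$accession[res$profiles$regulated], reg_true)
  # cluster assigned iff qc_pass and regulated
  has_cl <- !is.na(res$profiles$cluster)
  expect_identical(has_cl, res$profiles$qc_pass & res$profiles$regulated)
})
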