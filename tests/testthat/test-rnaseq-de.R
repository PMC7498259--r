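test_that("RPM normalization is exact arithmetic and conserves column totals", {
  m <- matrix(c(10, 90, 900), ncol = 1,
              dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(as.vector(normalize_rpm(m)), c(10000, 90000, 900000))
  m2 <- matrix(c(5, 5e6 - 5), ncol = 1, dimnames = list(c("g", "rest"), "s"))
  expect_equal(normalize_rpm(m2)["g", "s"], 1.0)
  set.seed(1)
  r <- matrix(rpois(20 * 6, 50), 20, 6,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:6)))
  expect_equal(unname(colSums(normalize_rpm(r))), rep(1e6, 6))
  r[, 3] <- 0
  expect_error(normalize_rpm(r), "s3")
})

test_that("detection filter applies the < min_samples rule exactly", {
  m <- matrix(1, 3, 12, dimnames = list(c("keep5", "drop4", "full"),
                                        paste0("s", 1:12)))
  m["keep5", 6:12] <- 0   # nonzero in 5 samples -> kept
  m["drop4", 5:12] <- 0   # nonzero in 4 samples -> removed
  f <- filter_low_detection(m, 5)
  expect_setequal(rownames(f$kept), c("keep5", "full"))
  expect_identical(f$removed, "drop4")
  # no zeros -> identity
  m2 <- matrix(1:24, 4, 6, dimnames = list(paste0("g", 1:4), NULL))
  expect_identical(filter_low_detection(m2, 5)$kept, m2)
  expect_warning(filter_low_detection(m2, 7), "exceeds")
})

test_that("detection filter agrees with an exhaustive recount", {
  set.seed(42)
  m <- matrix(rbinom(50 * 12, 1, 0.4) * rpois(50 * 12, 20), 50, 12,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:12)))
  f <- filter_low_detection(m, 5)
  brute <- vapply(seq_len(nrow(m)), function(i) sum(m[i, ] != 0) >= 5,
                  logical(1))
  expect_setequal(rownames(f$kept), rownames(m)[brute])
})

test_that("nested ANOVA matches lm()/anova() gene by gene", {
  set.seed(11)
  d <- default_design()
  expr <- matrix(rnorm(8 * 12, 100, 10), 8, 12,
                 dimnames = list(paste0("g", 1:8), d$sample_id))
  fit <- fit_gene_model(expr, d)
  for (i in seq_len(nrow(expr))) {
    a <- anova(lm(expr[i, ] ~ bio_rep + bio_rep:tech_rep + timepoint,
                  data = d))
    expect_equal(fit$anova_F[i], a["timepoint", "F value"], tolerance = 1e-10)
    expect_equal(fit$anova_p[i], a["timepoint", "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("degenerate genes are flagged instead of crashing", {
  d <- default_design()
  # constant expression
  f1 <- fit_gene_model(rep(5, 12), d)
  expect_true(f1$degenerate)
  expect_true(is.na(f1$anova_p))
  # exact timepoint means, zero residuals (infinite F limit)
  y <- c(day1 = 1, day3 = 2, day7 = 5)[as.character(d$timepoint)]
  f2 <- fit_gene_model(y, d)
  expect_true(f2$degenerate)
  pw <- tukey_pairwise(matrix(y, 1, dimnames = list("g", d$sample_id)), d)
  expect_true(all(is.na(pw$tukey_p)))
})

test_that("ANOVA p agrees with a within-stratum permutation oracle", {
  set.seed(19)
  d <- default_design()
  y <- rnorm(12, 50, 5) + 3 * (d$timepoint == "day7")
  f_stat <- function(tp) {
    dd <- d; dd$timepoint <- tp
    xf <- model.matrix(~ timepoint + bio_rep + bio_rep:tech_rep, dd)
    xr <- model.matrix(~ bio_rep + bio_rep:tech_rep, dd)
    rf <- sum(qr.resid(qr(xf), y)^2)
    rr <- sum(qr.resid(qr(xr), y)^2)
    ((rr - rf) / 2) / (rf / (12 - qr(xf)$rank))
  }
  f_obs <- f_stat(d$timepoint)
  # permute timepoint labels within each (bio_rep, tech_rep) cell
  cells <- split(seq_len(12), interaction(d$bio_rep, d$tech_rep))
  n_perm <- 10000
  f_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    tp <- d$timepoint
    for (cl in cells) tp[cl] <- sample(tp[cl])
    f_perm[b] <- f_stat(tp)
  }
  p_perm <- mean(f_perm >= f_obs)
  p_par <- fit_gene_model(y, d)$anova_p
  mc_se <- sqrt(p_perm * (1 - p_perm) / n_perm)
  # parametric and permutation p agree up to MC error plus a small
  # finite-sample allowance (n = 12)
  expect_lt(abs(p_par - p_perm), 3 * mc_se + 0.025)
})

test_that("timepoint F is invariant to biological-replicate relabeling", {
  set.seed(23)
  d <- default_design()
  y <- matrix(rnorm(5 * 12, 10), 5, 12,
              dimnames = list(paste0("g", 1:5), d$sample_id))
  d2 <- d
  d2$bio_rep <- factor(ifelse(d$bio_rep == "A", "B", "A"))
  expect_equal(fit_gene_model(y, d)$anova_F, fit_gene_model(y, d2)$anova_F,
               tolerance = 1e-10)
})

test_that("Tukey contrasts match TukeyHSD and report the three pairs", {
  set.seed(31)
  d <- default_design()
  y <- rnorm(12, 20, 3)
  pw <- tukey_pairwise(matrix(y, 1, dimnames = list("g", d$sample_id)), d)
  expect_setequal(pw$pair, c("d3_d1", "d7_d1", "d7_d3"))
  th <- TukeyHSD(aov(y ~ timepoint + bio_rep + bio_rep:tech_rep, data = d),
                 "timepoint")$timepoint
  ref <- data.frame(pair = c("d3_d1", "d7_d1", "d7_d3"),
                    diff = th[, "diff"], p = th[, "p adj"])
  expect_equal(pw$delta, ref$diff, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(pw$tukey_p, ref$p, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("equal timepoint means give Tukey p = 1", {
  d <- default_design()
  set.seed(5)
  y0 <- rnorm(12)
  y <- y0 - ave(y0, d$timepoint)  # equal timepoint means, noisy otherwise
  pw <- tukey_pairwise(matrix(y, 1, dimnames = list("g", d$sample_id)), d)
  expect_equal(pw$delta, rep(0, 3))
  expect_equal(pw$tukey_p, rep(1, 3))
})

test_that("Tukey p dominates the unadjusted pairwise t-test p", {
  set.seed(37)
  d <- default_design()
  for (i in 1:20) {
    y <- rnorm(12, 10, 2)
    fit <- fit_gene_model(y, d)
    pw <- tukey_pairwise(matrix(y, 1, dimnames = list("g", d$sample_id)), d)
    n_per <- 4
    t_stat <- abs(pw$delta) / sqrt(fit$sigma2 * 2 / n_per)
    p_t <- 2 * pt(t_stat, fit$df2, lower.tail = FALSE)
    expect_true(all(pw$tukey_p >= p_t - 1e-12))
  }
})

test_that("BH adjustment follows the step-up closed form", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(0.05, 7)), rep(0.05, 7))
  expect_error(adjust_bh(c(0.5, 1.2)), "0, 1")
  # NA (degenerate) entries propagate and shrink the family
  p <- c(0.01, NA, 0.04)
  out <- adjust_bh(p)
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], p.adjust(c(0.01, 0.04), "BH"))
  # random vectors: equals sorted-cummin construction, monotone, >= raw
  set.seed(41)
  for (i in 1:25) {
    p <- runif(sample(5:60, 1))
    out <- adjust_bh(p)
    o <- order(p); m <- length(p)
    oracle <- pmin(1, rev(cummin(rev(m / seq_len(m) * sort(p)))))[order(o)]
    expect_equal(out, oracle)
    expect_true(all(out >= p))
    expect_true(all(diff(out[o]) >= -1e-15))
  }
})

test_that("DE calls use a strict threshold and disjoint directions", {
  res <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"), pair = "d7_d1",
    delta = c(2, -2, 3, 1), bh_p = c(0.049, 0.01, 0.05, 1))
  calls <- call_de(res, alpha = 0.05)
  expect_identical(calls$up, "a")        # 0.05 exactly is NOT called
  expect_identical(calls$down, "b")
  expect_length(intersect(calls$up, calls$down), 0)
  res$bh_p <- 1
  empty <- call_de(res)
  expect_length(empty$up, 0); expect_length(empty$down, 0)
  expect_error(call_de(res, alpha = 1.5), "alpha")
})

test_that("the DE stage recovers planted truth on the packaged fixture", {
  fx <- load_fixture()
  de <- run_rnaseq_de(fx$counts, fx$design, scale = "log2")
  calls <- call_de(de$results, 0.05, "d7_d1")
  truth <- fx$rna_truth
  up_true <- truth$gene_id[truth$direction == "up"]
  down_true <- truth$gene_id[truth$direction == "down"]
  called <- c(calls$up, calls$down)
  tp <- sum(called %in% truth$gene_id[truth$is_de])
  expect_gt(tp / sum(truth$is_de), 0.8)           # recall
  expect_lt((length(called) - tp) / max(1, length(called)), 0.2)  # FDR
  # every truly DE gene that is called carries the planted direction
  expect_true(all(intersect(calls$up, truth$gene_id[truth$is_de]) %in%
                    up_true))
  expect_true(all(intersect(calls$down, truth$gene_id[truth$is_de]) %in%
                    down_true))
})
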