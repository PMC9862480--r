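test_that("spearman_rho handles monotone transforms and rank arithmetic", {
  x <- c(0.3, 1.1, 2.0, 3.5, 7.2, 9.9)
  expect_identical(spearman_rho(x, 2 * x + 1)$rho, 1)
  expect_identical(spearman_rho(x, -x)$rho, -1)
  # invariance under strictly monotone transforms of both vectors
  y <- c(5, 1, 4, 2, 6, 3)
  expect_equal(spearman_rho(exp(x), y^3)$rho, spearman_rho(x, y)$rho)
  sp <- spearman_rho(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(sp$rho, 0.8, tolerance = 1e-12)  # 1 - 6*4/(5*24)
  expect_equal(sp$rho, oracle_spearman_d2(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5)))
  # t-approximation p value
  tval <- 0.8 * sqrt(3 / (1 - 0.64))
  expect_equal(sp$p, 2 * stats::pt(-tval, 3), tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 2:1), "at least 3")
})

test_that("bland_altman matches hand formulas, including the LoA identity", {
  a <- c(1.1, 2.1, 3.1); b <- c(1.0, 2.0, 3.0)
  ba <- bland_altman(a, b)
  expect_equal(ba$bias, 0.1)
  expect_equal(ba$sd, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(0.1, 0.1))
  ba2 <- bland_altman(c(0, 1, 2), c(1, 1, 1))  # d = -1, 0, 1
  expect_equal(ba2$bias, 0)
  expect_equal(ba2$sd, 1)
  expect_equal(c(ba2$loa_low, ba2$loa_high), c(-1.96, 1.96))
  ba3 <- bland_altman(a, a)
  expect_equal(c(ba3$bias, ba3$loa_low, ba3$loa_high), c(0, 0, 0))
  # symmetry
  set.seed(2)
  p <- random_pair(15)
  expect_equal(bland_altman(p$a, p$b)$bias, -bland_altman(p$b, p$a)$bias)
})

test_that("icc_agreement reproduces reference values and penalizes bias", {
  # fixture frozen from an independent two-way ANOVA implementation
  # (ICC(A,1) on the same data agrees to 1e-10)
  a2 <- c(1, 2, 3, 4, 5, 6); b2 <- c(2, 1, 4, 3, 7, 5)
  ic <- icc_agreement(a2, b2)
  expect_equal(ic$icc, 0.8101265823, tolerance = 1e-9)
  # reference CI known to 2 decimals only
  expect_lt(max(abs(c(ic$ci_low, ic$ci_high) - c(0.10, 0.97))), 0.0051)
  expect_equal(ic$icc, oracle_icc_aov(a2, b2), tolerance = 1e-10)
  # perfect agreement
  ic1 <- icc_agreement(a2, a2)
  expect_identical(ic1$icc, 1)
  expect_identical(c(ic1$ci_low, ic1$ci_high), c(1, 1))
  # absolute agreement penalizes a constant offset (consistency would not)
  shifted <- icc_agreement(a2, a2 + 10)
  expect_lt(shifted$icc, 1)
  expect_lt(shifted$icc, icc_agreement(a2, a2 + 0.01)$icc)
  # swapping the pair leaves ICC unchanged
  expect_equal(icc_agreement(b2, a2)$icc, ic$icc, tolerance = 1e-12)
  expect_error(icc_agreement(rep(2, 6), rep(2, 6)), "zero total variance")
})

test_that("icc_agreement matches the larger frozen cross-check fixture", {
  # fixture regenerated deterministically; reference ICC frozen from an
  # independent mixed-model implementation (agrees to 1e-10)
  set.seed(42)
  a <- round(stats::rnorm(12, 10, 2), 3)
  b <- round(a + stats::rnorm(12, 0.5, 1), 3)
  ic <- icc_agreement(a, b)
  expect_equal(ic$icc, 0.8263649444, tolerance = 1e-9)
  # reference CI known to 2 decimals only
  expect_lt(max(abs(c(ic$ci_low, ic$ci_high) - c(0.50, 0.95))), 0.0051)
})

test_that("interpret_icc maps bands with edges going to the higher band", {
  expect_identical(interpret_icc(0.904), "excellent")
  expect_identical(interpret_icc(0.770), "good")
  expect_identical(interpret_icc(0.39), "poor")
  expect_identical(interpret_icc(c(-0.5, 0.40, 0.54, 0.55, 0.69, 0.70,
                                   0.84, 0.85, 1.0)),
                   c("poor", "weak", "weak", "moderate", "moderate", "good",
                     "good", "excellent", "excellent"))
  expect_error(interpret_icc(1.2), "\\[-1, 1\\]")
})

test_that("wilcoxon_signed_rank is exact for small n and monotone in evidence", {
  w <- wilcoxon_signed_rank(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
  expect_identical(w$statistic, 0)
  expect_equal(w$p, 2 / 32)
  expect_identical(w$method, "exact enumeration")
  # tied fixture: exact p frozen from full 2^n sign-pattern enumeration
  a <- c(5, 3, 8, 9, 4, 7, 6, 2); b <- c(4, 5, 6, 5, 4.5, 7.5, 2, 1)
  wt <- wilcoxon_signed_rank(a, b)
  expect_equal(wt$p, 0.1953125, tolerance = 1e-12)
  expect_equal(wt$p, oracle_wilcoxon_enum(a, b), tolerance = 1e-12)
  # flipping one sign weakens the evidence
  d <- c(1, 2, 3, 4, 5)
  p_all <- wilcoxon_signed_rank(10 + d, rep(10, 5))$p
  d2 <- c(-1, 2, 3, 4, 5)
  p_flip <- wilcoxon_signed_rank(10 + d2, rep(10, 5))$p
  expect_gt(p_flip, p_all)
  expect_error(wilcoxon_signed_rank(1:5, 1:5), "degenerate")
  # zeros are dropped, not ranked
  wz <- wilcoxon_signed_rank(c(1, 2, 3, 5), c(1, 1, 1, 1))
  expect_identical(wz$n_zero, 1L)
  expect_identical(wz$n, 3L)
})

test_that("statistics agree with brute-force references on random vectors", {
  set.seed(123)
  for (i in 1:50) {
    n <- sample(5:20, 1)
    p <- random_pair(n)
    # spearman vs the sum-of-d^2 formula (tie-free continuous draws)
    expect_equal(spearman_rho(p$a, p$b)$rho, oracle_spearman_d2(p$a, p$b),
                 tolerance = 1e-9)
    # and vs base R's estimator
    expect_equal(spearman_rho(p$a, p$b)$rho,
                 unname(stats::cor(p$a, p$b, method = "spearman")),
                 tolerance = 1e-9)
    ba <- bland_altman(p$a, p$b)
    ref <- oracle_bland_altman(p$a, p$b)
    expect_equal(c(ba$bias, ba$sd, ba$loa_low, ba$loa_high), unname(ref),
                 tolerance = 1e-9)
    expect_equal(icc_agreement(p$a, p$b)$icc, oracle_icc_aov(p$a, p$b),
                 tolerance = 1e-9)
    if (n <= 12) {
      expect_equal(wilcoxon_signed_rank(p$a, p$b)$p,
                   oracle_wilcoxon_enum(p$a, p$b), tolerance = 1e-9)
    }
  }
})

test_that("the exact Wilcoxon branch agrees with base R when ties are absent", {
  set.seed(55)
  for (i in 1:10) {
    n <- sample(6:15, 1)
    p <- random_pair(n)
    ours <- wilcoxon_signed_rank(p$a, p$b)
    ref <- stats::wilcox.test(p$a, p$b, paired = TRUE, exact = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("build_report emits six comparisons and survives degenerate rows", {
  coh <- make_cohort(cohort_spec(n_patients = 40, seed = 6))
  rep <- build_report(coh, predict_cohort(coh))
  expect_identical(nrow(rep), 6L)
  expect_true(all(rep$loa_low == rep$bias - 1.96 * rep$sd_diff))
  expect_true(all(rep$loa_high == rep$bias + 1.96 * rep$sd_diff))
  expect_true(all(rep$icc_ci_low <= rep$icc & rep$icc <= rep$icc_ci_high))
  expect_true(all(rep$rho >= -1 & rep$rho <= 1))
  # noise-free cohort: WAL-vs-measured rows are perfect, Wilcoxon degenerate
  coh0 <- make_cohort(cohort_spec(n_patients = 20, sigma = 0, seed = 6))
  rep0 <- build_report(coh0, predict_cohort(coh0))
  wal_rows <- grep("WAL.*postoperative", rep0$comparison)
  expect_identical(rep0$rho[wal_rows], c(1, 1))
  expect_identical(rep0$icc[wal_rows], c(1, 1))
  expect_identical(rep0$loa_low[wal_rows], c(0, 0))
  expect_identical(rep0$loa_high[wal_rows], c(0, 0))
  expect_true(all(is.na(rep0$wilcoxon_p[wal_rows])))
  # misaligned inputs rejected
  expect_error(build_report(coh, predict_cohort(coh)[c(2:40, 1), ]),
               "not aligned")
})
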