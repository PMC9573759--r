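test_that("mean bias, CI and paired t match hand computation", {
  # differences 5, 6, 7: bias 6, t = 6 / (1/sqrt(3)) = 10.392, df = 2
  m <- c(10, 20, 30)
  e <- m + c(5, 6, 7)
  out <- mean_bias_ci(m, e)
  expect_equal(out$bias, 6)
  expect_equal(out$ci, c(3.5158623, 8.4841377), tolerance = 1e-6)
  expect_equal(out$p, 0.0091326, tolerance = 1e-4)

  ident <- mean_bias_ci(m, m)
  expect_equal(ident$bias, 0)
  expect_true(ident$exact_agreement)
  expect_equal(ident$p, 1)

  shift <- mean_bias_ci(m, m + 4)  # constant difference
  expect_equal(shift$bias, 4)
  expect_equal(shift$ci, c(4, 4))
})

test_that("Pearson r matches hand computation; identical estimates give p = 1", {
  r <- pearson_with_comparison(1:20 + 0.5 * rnorm(20, 0, 1e-9),
                               est_a = 1:20, est_b = 1:20)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)
  # r of {(1,1),(2,2),(3,4)} = 3/sqrt(28/3) = 0.98198
  expect_equal(cor(c(1, 2, 3), c(1, 2, 4)), 0.9819805, tolerance = 1e-6)
  expect_error(pearson_with_comparison(rep(1, 12), 1:12, 12:1), "constant")
})

test_that("a perfectly informative estimator beats noise decisively at n = 200", {
  set.seed(41)
  meas <- rnorm(200, 180, 60)
  noise <- rnorm(200, 180, 60)
  out <- pearson_with_comparison(meas, meas, noise)
  expect_equal(out$r_a, 1)
  expect_lt(out$p, 1e-10)
})

test_that("correlation-comparison decisions agree with a bootstrap oracle", {
  # oracle: percentile bootstrap of the correlation difference; decision at
  # alpha = 0.05 compared on instances spanning clear and null effects
  set.seed(57)
  n_boot <- 2000
  agree <- 0
  n_inst <- 20
  for (i in seq_len(n_inst)) {
    n <- 80
    x <- rnorm(n)
    # half the instances share the generating correlation (null true)
    d_a <- runif(1, 0.2, 1.2)
    d_b <- if (i %% 2 == 0) d_a else runif(1, 0.2, 1.2)
    a <- d_a * x + rnorm(n)
    b <- d_b * x + rnorm(n) * (1 + 0.2 * (i %% 3))
    test_p <- pearson_with_comparison(x, a, b)$p
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), ncol = n_boot)
    dr <- apply(idx, 2, function(j) cor(x[j], a[j]) - cor(x[j], b[j]))
    ci <- quantile(dr, c(0.025, 0.975))
    boot_sig <- ci[1] > 0 || ci[2] < 0
    agree <- agree + ((test_p < 0.05) == boot_sig)
  }
  expect_gte(agree, n_inst - 1)
})

test_that("ICC(A,1) matches hand ANOVA and the brute-force oracle", {
  # measured 1:4 vs estimated 11:14 -> MSR = 10/3, MSC = 200, MSE = 0,
  # ICC = (10/3) / (10/3 + (2/4)*200) = 1/31
  out <- icc_a1(c(1, 2, 3, 4, 5), c(11, 12, 13, 14, 15))
  expect_equal(out$icc, (5 - 0) / (5 + (2 / 5) * (250 - 0)))  # n=5 analogue
  out4 <- icc_a1(c(1, 2, 3, 4, 2.5), c(11, 12, 13, 14, 12.5))
  expect_equal(unname(out4$ms["MSE"]), 0)

  # perfect agreement
  p <- icc_a1(c(3, 9, 5, 7, 1), c(3, 9, 5, 7, 1))
  expect_equal(p$icc, 1)
  expect_equal(p$label, "excellent")

  # brute-force oracle: two-way ANOVA decomposition via aov() on >= 50
  # random instances
  set.seed(73)
  for (rep_i in 1:50) {
    n <- sample(5:40, 1)
    meas <- rnorm(n, 100, 25)
    est <- 0.8 * meas + rnorm(n, 10, 15)
    got <- icc_a1(meas, est)
    long <- data.frame(y = c(meas, est),
                       subj = factor(rep(seq_len(n), 2)),
                       rater = factor(rep(c("m", "e"), each = n)))
    av <- summary(aov(y ~ subj + rater, data = long))[[1]]
    MSR <- av["subj", "Mean Sq"]; MSC <- av["rater", "Mean Sq"]
    MSE <- av["Residuals", "Mean Sq"]
    icc_oracle <- (MSR - MSE) / (MSR + MSE + (2 / n) * (MSC - MSE))
    expect_equal(got$icc, icc_oracle, tolerance = 1e-9)
  }
})

test_that("ICC confidence interval brackets the point estimate", {
  set.seed(74)
  meas <- rnorm(100, 100, 25)
  est <- meas + rnorm(100, 5, 20)
  out <- icc_a1(meas, est)
  expect_lt(out$ci[1], out$icc)
  expect_gt(out$ci[2], out$icc)
  expect_true(out$ci[1] > -1 && out$ci[2] <= 1)
})

test_that("a constant offset leaves Pearson r unchanged but lowers ICC(A,1)", {
  set.seed(75)
  meas <- rnorm(200, 100, 25)
  est <- meas + rnorm(200, 0, 10)
  base_r <- cor(meas, est)
  base_icc <- icc_a1(meas, est)$icc
  off_r <- cor(meas, est + 30)
  off_icc <- icc_a1(meas, est + 30)$icc
  expect_equal(off_r, base_r, tolerance = 1e-12)
  expect_lt(off_icc, base_icc)
})

test_that("ICC degenerate inputs are flagged", {
  expect_error(icc_a1(rep(5, 6), rep(7, 6)), "between-subject")
})

test_that("P30 and cutoff proportions follow their inclusive-boundary definitions", {
  meas <- c(100, 100, 100, 100)
  est <- c(129, 131, 70, 100)
  expect_equal(p30(meas, est), 75)
  expect_equal(p30(meas, meas), 100)
  expect_equal(p30(meas, 1.31 * meas), 0)
  expect_error(p30(c(0, 100), c(1, 1)), "measured > 0")

  expect_equal(proportion_within(c(100, 100), c(109, 120), "relative", 0.10), 50)
  expect_equal(proportion_within(c(100, 100), c(110, 80), "absolute", 17.1), 50)
  expect_equal(proportion_within(meas, meas, "relative", 0), 100)
  expect_error(proportion_within(meas, est, "relative", -0.1), "cutoff")

  # P30 is exactly the relative proportion at 0.30
  set.seed(81)
  m <- runif(300, 50, 250); e <- m * runif(300, 0.5, 1.6)
  expect_identical(p30(m, e), proportion_within(m, e, "relative", 0.30))
})

test_that("cutoff curves are non-decreasing and saturate at 100%", {
  set.seed(82)
  m <- runif(500, 50, 250); e <- m + rnorm(500, 0, 40)
  grid <- seq(0, 2, by = 0.05)
  curve_rel <- proportion_within(m, e, "relative", grid)
  expect_true(all(diff(curve_rel) >= 0))
  expect_equal(proportion_within(m, e, "relative", 1e9), 100)
  curve_abs <- proportion_within(m, e, "absolute", seq(0, 200, by = 5))
  expect_true(all(diff(curve_abs) >= 0))
})

test_that("Bland-Altman limits follow the 1.96 convention and share the bias estimate", {
  m <- c(10, 20, 30)
  ba <- bland_altman(m, m + c(-1, 0, 1))  # SD of diffs = 1
  expect_equal(ba$bias, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(-1.96, 1.96))
  ident <- bland_altman(m, m)
  expect_equal(c(ident$bias, ident$loa_low, ident$loa_high), c(0, 0, 0))

  # ~95% of normal differences fall inside the limits
  set.seed(83)
  meas <- rnorm(10000, 180, 50)
  est <- meas + rnorm(10000, 3, 25)
  ba2 <- bland_altman(meas, est)
  inside <- mean(ba2$points$diff > ba2$loa_low & ba2$points$diff < ba2$loa_high)
  expect_equal(inside, 0.95, tolerance = 0.01)
  # bias identical to the mean-bias point estimate
  expect_equal(ba2$bias, mean_bias_ci(meas, est)$bias, tolerance = 1e-12)
})

test_that("all agreement metrics are invariant to record order", {
  set.seed(84)
  m <- runif(120, 80, 250); e <- m + rnorm(120, 5, 30)
  perm <- sample.int(120)
  expect_equal(mean_bias_ci(m, e)$ci, mean_bias_ci(m[perm], e[perm])$ci)
  expect_equal(icc_a1(m, e)$icc, icc_a1(m[perm], e[perm])$icc)
  expect_equal(p30(m, e), p30(m[perm], e[perm]))
  ba_a <- bland_altman(m, e); ba_b <- bland_altman(m[perm], e[perm])
  expect_equal(c(ba_a$loa_low, ba_a$loa_high), c(ba_b$loa_low, ba_b$loa_high))
})

test_that("validate_all mirrors the published table structure", {
  co <- generate_cohort(cohort_params(n = 400, seed = 91))
  val <- validate_all(co)
  expect_s3_class(val, "validation_table")
  expect_equal(sum(val$analyte == "na"), 4)  # new, kawasaki, intersalt, tanaka
  expect_equal(sum(val$analyte == "k"), 3)   # no INTERSALT potassium
  expect_true(all(val$p30 >= 0 & val$p30 <= 100))
  expect_true(all(val$bias_lo <= val$bias & val$bias <= val$bias_hi))
  expect_true(all(is.na(val$r_vs_ref_p[val$method == "new"])))
  expect_true(all(!is.na(val$r_vs_ref_p[val$method != "new"])))
  cuts <- attr(val, "cutoffs")
  expect_setequal(unique(cuts$mode), c("relative", "absolute"))
  expect_equal(unique(cuts$cutoff[cuts$analyte == "na" &
                                    cuts$mode == "absolute"]), 17.1)
  expect_equal(unique(cuts$cutoff[cuts$analyte == "k" &
                                    cuts$mode == "absolute"]), 12.8)
  ba <- attr(val, "bland_altman")
  expect_true("na_new" %in% names(ba))
})

test_that("validate_all on the perfect-agreement fixture reports ideal metrics", {
  co <- make_fixture("perfect_agreement")
  val <- validate_all(co, methods = "new", reference = "new")
  new_na <- val[val$analyte == "na" & val$method == "new", ]
  expect_equal(new_na$bias, 0, tolerance = 1e-12)
  expect_equal(new_na$pearson_r, 1, tolerance = 1e-12)
  expect_equal(new_na$icc, 1, tolerance = 1e-12)
  expect_equal(new_na$p30, 100)
})

test_that("sample-size planning follows the Fisher-z formula", {
  expect_equal(sample_size_correlation(0.32, 0.05, 0.90, 0.10), 110L)
  # exclusion 0: uninflated
  expect_equal(sample_size_correlation(0.32, 0.05, 0.90, 0), 99L)
  # near-perfect correlation: formula floor of 4 before inflation
  expect_equal(sample_size_correlation(0.999999, exclusion_rate = 0), 4L)
  expect_error(sample_size_correlation(0), "in \\(0, 1\\)")
  expect_error(sample_size_correlation(1), "in \\(0, 1\\)")
})
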