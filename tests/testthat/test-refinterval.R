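test_that("Tukey's rule flags values beyond 1.5 IQR from the quartiles", {
  # quartiles 1 and 3 -> upper fence 6; the point at 7 is flagged
  x <- c(0.5, 1, 1.5, 2, 2.5, 3, 3.5, 7)
  res <- tukey_outliers(x)
  expect_equal(res$flagged, 7)
  expect_equal(sort(res$kept), sort(setdiff(x, 7)))
  # symmetric sample with no extremes
  res2 <- tukey_outliers(qnorm(ppoints(50)))
  expect_length(res2$flagged, 0)
  expect_error(tukey_outliers(c(1, 2, 3)), "at least 4")
})

test_that("a planted extreme in a skewed reference sample is screened out", {
  vals <- withr::with_seed(50, exp(rnorm(60, -0.2, 0.55)))
  vals <- tukey_outliers(vals)$kept        # remove any natural extremes
  planted <- max(vals) * 4
  ri <- reference_interval(c(vals, planted), B = 500, seed = 51)
  expect_length(ri$outliers_removed, 1)
  expect_equal(ri$outliers_removed, planted)
  expect_equal(ri$n_used, length(vals))
})

test_that("Box-Cox profile likelihood recovers the generating transform", {
  x_norm <- withr::with_seed(52, rnorm(500, 50, 5))
  expect_lt(abs(boxcox_fit(x_norm)$lambda - 1), 0.3)
  x_lnorm <- withr::with_seed(53, exp(rnorm(500, 1, 0.5)))
  expect_lt(abs(boxcox_fit(x_lnorm)$lambda), 0.2)
  # transform/back-transform identity
  x <- c(0.2, 1, 2.7, 14)
  for (lam in c(-1, 0, 0.5, 1))
    expect_equal(boxcox_inverse(boxcox_transform(x, lam), lam), x,
                 tolerance = 1e-12)
  expect_error(boxcox_fit(c(-1, 2, 3)), "positive")
})

test_that("Box-Cox lambda agrees with the MASS profile", {
  skip_if_not_installed("MASS")
  x <- withr::with_seed(54, exp(rnorm(300, 0.5, 0.4)))
  ours <- boxcox_fit(x)$lambda
  bc <- MASS::boxcox(x ~ 1, lambda = seq(-3, 3, 0.01), plotit = FALSE)
  theirs <- bc$x[which.max(bc$y)]
  expect_equal(ours, theirs, tolerance = 0.011)
})

test_that("robust limits are consistent for Gaussian data and resist gross contamination", {
  y <- withr::with_seed(55, rnorm(1e4))
  rl <- robust_limits(y)
  expect_lt(abs(rl$lower - (-1.96)), 0.05)
  expect_lt(abs(rl$upper - 1.96), 0.05)
  # 2% contamination at +10 barely moves the robust upper limit
  y2 <- withr::with_seed(56, rnorm(980))
  contaminated <- c(y2, rep(10, 20))
  clean_par <- mean(y2) + 1.96 * sd(y2)
  contam_par <- mean(contaminated) + 1.96 * sd(contaminated)
  parametric_shift <- contam_par - clean_par
  robust_shift <- robust_limits(contaminated)$upper - robust_limits(y2)$upper
  expect_lt(abs(robust_shift), 0.25 * abs(parametric_shift))
  # degenerate input
  rl0 <- robust_limits(rep(3, 50))
  expect_true(rl0$degenerate)
  expect_equal(c(rl0$lower, rl0$upper), c(3, 3))
})

test_that("robust limits are equivariant under affine maps and contain the median", {
  y <- withr::with_seed(57, rnorm(500, 2, 1.5))
  rl <- robust_limits(y)
  a <- 3.2; b <- 0.7
  rl2 <- robust_limits(a + b * y)
  expect_equal(rl2$lower, a + b * rl$lower, tolerance = 1e-8)
  expect_equal(rl2$upper, a + b * rl$upper, tolerance = 1e-8)
  expect_true(rl$lower < median(y) && median(y) < rl$upper)
})

test_that("the bootstrap is deterministic given a seed and covers the truth", {
  vals <- withr::with_seed(58, rnorm(120, 10, 2))
  ci_a <- bootstrap_limit_ci(vals, B = 500, seed = 59, transform = "none")
  ci_b <- bootstrap_limit_ci(vals, B = 500, seed = 59, transform = "none")
  expect_identical(ci_a$ci_lower, ci_b$ci_lower)
  expect_identical(ci_a$ci_upper, ci_b$ci_upper)
  expect_error(bootstrap_limit_ci(vals, B = 500), "seed")
  y <- withr::with_seed(60, rnorm(1000))
  ci <- bootstrap_limit_ci(y, B = 1000, seed = 61, transform = "none")
  expect_true(ci$ci_upper[1] <= 1.96 && 1.96 <= ci$ci_upper[2])
})

test_that("a 60-cat skewed sample yields inadequately wide limit CIs", {
  # lognormal geometry emulating lean-cat HOMA-IR (median ~0.8)
  vals <- withr::with_seed(62, exp(rnorm(60, log(0.8), 0.6)))
  ri <- reference_interval(vals, B = 1000, seed = 63)
  expect_false(ri$ci_width_adequate)
  # the interval still contains the sample median and brackets the CIs
  expect_true(ri$lower < median(vals) && median(vals) < ri$upper)
  expect_true(ri$ci_lower[1] <= ri$lower && ri$lower <= ri$ci_lower[2])
  expect_true(ri$ci_upper[1] <= ri$upper && ri$upper <= ri$ci_upper[2])
})

test_that("the full pipeline approximates the generating quantiles", {
  # lognormal fixture: analytic 2.5th/97.5th percentiles as oracle
  mu <- log(0.8); sig <- 0.55
  vals <- withr::with_seed(64, exp(rnorm(400, mu, sig)))
  ri <- reference_interval(vals, B = 500, seed = 65)
  expect_lt(abs(ri$lower - qlnorm(0.025, mu, sig)) / qlnorm(0.025, mu, sig),
            0.10)
  # the upper limit sits below the untrimmed parametric quantile because
  # Tukey screening removes part of the genuine lognormal right tail
  expect_gt(ri$upper, quantile(vals, 0.90))
  expect_lt(ri$upper, qlnorm(0.995, mu, sig))
  # bootstrap CIs shrink with n on the same generating law
  vals_big <- withr::with_seed(66, exp(rnorm(1600, mu, sig)))
  ri_big <- reference_interval(vals_big, B = 500, seed = 67)
  expect_lt(diff(ri_big$ci_upper), diff(ri$ci_upper))
})
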