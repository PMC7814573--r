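test_that("exact rank-sum p-values match exhaustive enumeration", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_two_sided, 0.1)
  # exhaustive check over all group sizes up to 6, tie-free data
  pool <- withr::with_seed(80, runif(12))
  for (n1 in 2:6) for (n2 in 2:6) {
    x <- pool[seq_len(n1)]
    y <- pool[n1 + seq_len(n2)]
    res <- wilcoxon_rank_sum(x, y)
    expect_equal(res$method, "exact")
    expect_equal(res$p_two_sided, oracle_wilcoxon_exact(x, y),
                 info = sprintf("n1=%d n2=%d", n1, n2))
  }
})

test_that("rank-sum handles ties, identical groups and degenerate input", {
  x <- c(1, 2, 2, 3)
  res <- wilcoxon_rank_sum(x, x)
  expect_equal(res$p_two_sided, 1)
  expect_equal(res$method, "normal_approx_tie_corrected")
  expect_warning(res0 <- wilcoxon_rank_sum(rep(2, 5), rep(2, 4)),
                 "identical")
  expect_equal(res0$p_two_sided, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
  # descriptives use type-7 quartiles
  d <- wilcoxon_rank_sum(1:9, 11:19)$group1
  expect_equal(c(d$median, d$q1, d$q3), c(5, 3, 7))
})

test_that("rank-sum p is invariant under strictly monotone transforms", {
  withr::with_seed(81, {
    x <- rlnorm(15); y <- rlnorm(18, 0.5)
  })
  p0 <- wilcoxon_rank_sum(x, y)$p_two_sided
  expect_equal(wilcoxon_rank_sum(log(x), log(y))$p_two_sided, p0)
  expect_equal(wilcoxon_rank_sum(x^3, y^3)$p_two_sided, p0)
  expect_equal(wilcoxon_rank_sum(-1 / x, -1 / y)$p_two_sided, p0)
})

test_that("Noether's approximation links n, power and P(X<Y)", {
  res <- noether(73, 77, alpha = 0.05, power = 0.80)
  expect_equal(round(res$p_doubleprime, 2), 0.63)
  # self-inverse: feeding the solved p'' back returns the power
  back <- noether(73, 77, alpha = 0.05, p_doubleprime = res$p_doubleprime)
  expect_equal(round(back$power, 2), 0.80)
  # null limit: power tends to alpha as p'' -> 0.5
  null_power <- noether(73, 77, p_doubleprime = 0.5 + 1e-9)$power
  expect_equal(null_power, 0.05, tolerance = 1e-5)
  expect_error(noether(73, 77, p_doubleprime = 0.4), "0.5")
  expect_error(noether(73, 77), "exactly one")
  expect_error(noether(73, 77, power = 0.8, p_doubleprime = 0.6),
               "exactly one")
})

test_that("the rank-sum test attains the Noether-predicted power", {
  # groups of 73 and 77 lognormal values with a shift chosen so that
  # P(X < Y) = 0.63: power at alpha = 0.05 should be close to 80%
  pp <- 0.63
  sd_ln <- 0.8
  delta <- sqrt(2) * sd_ln * qnorm(pp)    # ln-scale shift giving P(X<Y)=p''
  B <- 400
  rej <- withr::with_seed(82, {
    sum(vapply(seq_len(B), function(b) {
      x <- exp(rnorm(73, 0, sd_ln))
      y <- exp(rnorm(77, delta, sd_ln))
      wilcoxon_rank_sum(x, y)$p_two_sided < 0.05
    }, logical(1)))
  })
  expect_lt(abs(rej / B - 0.80), 0.06)
})

test_that("ln-regression recovers noiseless slopes exactly", {
  x <- seq(20, 60, length.out = 68)
  fit <- suppressWarnings(ln_regression(exp(0.0262 * x), x))
  expect_equal(fit$beta, 0.0262, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$pct_change_per_10, 100 * (exp(0.262) - 1),
               tolerance = 1e-8)
  expect_error(ln_regression(c(-1, 2, 3), 1:3), "positive")
  expect_error(ln_regression(c(1, 2, 3), rep(1, 3)), "zero variance")
})

test_that("slope CIs cover the truth at the study geometry", {
  # n = 68, beta = 0.0262, noise tuned for R^2 near 0.15
  beta <- 0.0262
  B <- 400
  hits <- withr::with_seed(83, {
    sum(vapply(seq_len(B), function(b) {
      bf <- felir:::rtrunc_norm(68, 38, 11.9, c(15.3, 61.9))
      y <- exp(0.1 + beta * bf + rnorm(68, 0, 0.64))
      ci <- confint(ln_regression(y, bf)$fit)["predictor", ]
      ci[1] <= beta && beta <= ci[2]
    }, logical(1)))
  })
  expect_gte(hits / B, 0.93)
})

test_that("the slope p-value is uniform under a permuted predictor", {
  B <- 200
  ps <- withr::with_seed(84, {
    bf <- felir:::rtrunc_norm(68, 38, 11.9, c(15.3, 61.9))
    y <- exp(0.1 + 0.0262 * bf + rnorm(68, 0, 0.64))
    vapply(seq_len(B), function(b)
      ln_regression(y, sample(bf))$p_value, numeric(1))
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("an added covariate is reported as a pass-through regressor", {
  withr::with_seed(85, {
    bf <- felir:::rtrunc_norm(68, 38, 11.9, c(15.3, 61.9))
    loco <- rbinom(68, 1, 0.22)
    y <- exp(0.1 + 0.0262 * bf + rnorm(68, 0, 0.64))
  })
  fit <- ln_regression(y, bf, covariate = loco)
  expect_false(is.na(fit$covariate_p))
  expect_true(fit$covariate_p > 0.001)   # no true covariate effect
})

test_that("percent change per predictor delta follows exp(beta*delta)", {
  expect_equal(round(pct_change_per_delta(0.0262, 10)), 30)
  expect_equal(round(pct_change_per_delta(0.0225, 10)), 25)
  expect_equal(pct_change_per_delta(0, 7), 0)
  expect_equal(pct_change_per_delta(-0.05, 10), 100 * (exp(-0.5) - 1))
})

test_that("cohort summaries carry the clinical table shape", {
  cohort <- generate_cohort(n = 120, seed = 86)
  summ <- cohort_summary(cohort)
  expect_equal(summ$analyte, c("homa_ir", "insulin_mUL", "glucose_mmolL"))
  expect_true(all(summ$n_lean + summ$n_overweight == nrow(cohort)))
  expect_true(all(summ$p_value > 0 & summ$p_value <= 1))
  expect_true(all(summ$lean_q1 <= summ$lean_median &
                    summ$lean_median <= summ$lean_q3))
})
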