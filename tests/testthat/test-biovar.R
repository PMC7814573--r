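test_that("Cole's equation converts ln-scale SDs to CVs", {
  expect_equal(cv_from_sdln(0), 0)
  expect_equal(cv_from_sdln(0.48086), 51.0, tolerance = 1e-3)
  expect_equal(cv_from_sdln(0.0739), 7.4, tolerance = 1e-2)
  expect_error(cv_from_sdln(-0.1), "non-negative")
  # inverse relation and small-sd linear limit
  cv <- c(0.5, 5, 20, 51, 120)
  expect_equal(cv_from_sdln(sdln_from_cv(cv)), cv, tolerance = 1e-12)
  sd_small <- seq(0.001, 0.05, by = 0.001)
  rel <- abs(cv_from_sdln(sd_small) - 100 * sd_small) / cv_from_sdln(sd_small)
  expect_true(all(rel < 0.002))
  # strictly increasing
  expect_true(all(diff(cv_from_sdln(seq(0, 2, by = 0.01))) > 0))
})

test_that("REML reproduces nested-ANOVA closed forms on balanced designs", {
  s <- generate_biovar_series(n_cats = 4, n_occasions = 3,
                              n_replicates = 2, cv_g = 40, cv_i = 30,
                              cv_a = 8, grand_mean = 2, seed = 21)
  fit <- fit_nested_reml(s)
  oracle <- oracle_nested_anova(as.data.frame(s))
  expect_true(fit$converged)
  expect_equal(fit$sd2_G, oracle$sd2_G, tolerance = 1e-6)
  expect_equal(fit$sd2_I, oracle$sd2_I, tolerance = 1e-6)
  expect_equal(fit$sd2_A, oracle$sd2_A, tolerance = 1e-6)
})

test_that("REML agrees with lme4 when all components are positive", {
  skip_if_not_installed("lme4")
  s <- generate_biovar_series(seed = 11)
  fit <- fit_nested_reml(s)
  d <- as.data.frame(s)
  d$ly <- log(d$value)
  d$occ <- interaction(d$cat_id, d$occasion)
  m <- lme4::lmer(ly ~ 1 + (1 | cat_id) + (1 | occ), data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))
  vget <- function(g) vc$vcov[vc$grp == g]
  expect_equal(fit$sd2_G, vget("cat_id"), tolerance = 1e-5)
  expect_equal(fit$sd2_I, vget("occ"), tolerance = 1e-5)
  expect_equal(fit$sd2_A, vget("Residual"), tolerance = 1e-5)
  expect_equal(fit$log_restricted_likelihood, as.numeric(stats::logLik(m)),
               tolerance = 1e-6)
})

test_that("degenerate and unbalanced designs are handled", {
  # all observations identical -> zero components
  s0 <- biovar_series(cat_id = rep(1:3, each = 4),
                      occasion = rep(rep(1:2, each = 2), 3),
                      replicate = rep(1:2, 6), value = rep(2.5, 12))
  f0 <- fit_nested_reml(s0)
  expect_equal(c(f0$sd2_G, f0$sd2_I, f0$sd2_A), c(0, 0, 0))
  expect_true(f0$converged)

  # one missing replicate: restricted likelihood at the optimum must be at
  # least as high as at the balanced-formula (ANOVA-style) estimates
  s1 <- generate_biovar_series(seed = 22, drop_one_replicate = TRUE)
  f1 <- fit_nested_reml(s1)
  expect_true(f1$converged)
  df <- as.data.frame(s1)
  y <- log(df$value)
  catf <- factor(df$cat_id)
  occf <- factor(paste(df$cat_id, df$occasion))
  nll <- felir:::make_nll(y, catf, occf, balanced = FALSE)
  start <- felir:::nested_anova_estimates(y, catf, occf)
  expect_lte(nll(c(f1$sd2_G, f1$sd2_I, f1$sd2_A)), nll(unname(start)) + 1e-8)

  # design errors
  expect_error(fit_nested_reml(data.frame(cat_id = "a", occasion = 1:4,
                                          value = 1:4)), "design error")
  # no duplicates anywhere: analytical component not estimable
  s2 <- generate_biovar_series(n_replicates = 1, seed = 23)
  f2 <- fit_nested_reml(s2)
  expect_true(is.na(f2$sd2_A))
  expect_error(biovar_indices(f2), "not estimable")
})

test_that("balanced and general likelihood code paths agree", {
  s <- generate_biovar_series(n_cats = 5, n_occasions = 4, seed = 30)
  df <- as.data.frame(s)
  y <- log(df$value)
  catf <- factor(df$cat_id)
  occf <- factor(paste(df$cat_id, df$occasion))
  nb <- felir:::make_nll(y, catf, occf, balanced = TRUE)
  nd <- felir:::make_nll(y, catf, occf, balanced = FALSE)
  for (th in list(c(0.3, 0.1, 0.01), c(0.05, 0.4, 0.002),
                  c(-0.01, 0.2, 0.05)))
    expect_equal(nb(th), nd(th), tolerance = 1e-10)
})

test_that("Wald intervals are floored at zero and degenerate with zero SE", {
  s <- generate_biovar_series(seed = 11)
  fit <- fit_nested_reml(s)
  ci <- wald_ci_components(fit)
  expect_true(all(ci$cv_lower >= 0))
  expect_true(all(ci$cv_lower <= ci$cv & ci$cv <= ci$cv_upper))
  # small between-cat variance relative to its SE -> lower limit exactly 0
  s_low <- generate_biovar_series(n_cats = 3, cv_g = 5, cv_i = 50,
                                  cv_a = 7, seed = 31)
  ci_low <- suppressWarnings(wald_ci_components(fit_nested_reml(s_low)))
  expect_equal(ci_low$cv_lower[ci_low$component == "G"], 0)
  # zero SE degenerates to the point estimate
  fit0 <- fit
  fit0$vcov <- matrix(0, 3, 3, dimnames = list(c("G", "I", "A"),
                                               c("G", "I", "A")))
  ci0 <- wald_ci_components(fit0)
  expect_equal(ci0$cv_lower, ci0$cv)
  expect_equal(ci0$cv_upper, ci0$cv)
})

test_that("Wald CIs are calibrated in the asymptotic regime", {
  # balanced design large enough for the Wald argument; the dominant
  # component is the within-cat CV
  truth <- c(G = 20, I = 45, A = 8)
  B <- 400
  hits <- 0
  for (b in seq_len(B)) {
    s <- generate_biovar_series(n_cats = 40, n_occasions = 5,
                                n_replicates = 2, cv_g = truth["G"],
                                cv_i = truth["I"], cv_a = truth["A"],
                                seed = 5000 + b)
    ci <- suppressWarnings(wald_ci_components(fit_nested_reml(s)))
    r <- ci[ci$component == "I", ]
    hits <- hits + (r$cv_lower <= truth["I"] && truth["I"] <= r$cv_upper)
  }
  expect_gt(hits / B, 0.92)
  expect_lt(hits / B, 0.98)
})

test_that("index of individuality matches its definition", {
  expect_equal(round(index_of_individuality(52.3, 51.0, 7.4), 1), 1.0)
  expect_equal(round(index_of_individuality(52.1, 38.0, 6.6), 2), 1.35)
  expect_equal(index_of_individuality(0, 30, 5), 0)
  expect_error(index_of_individuality(10, 0, 0), "both be zero")
  # scale invariance
  withr::with_seed(40, for (i in 1:20) {
    cvs <- runif(3, 1, 80)
    k <- runif(1, 0.1, 10)
    expect_equal(index_of_individuality(k * cvs[1], k * cvs[2], k * cvs[3]),
                 index_of_individuality(cvs[1], cvs[2], cvs[3]),
                 tolerance = 1e-12)
  })
})

test_that("RCV is asymmetric on the natural scale with exact reciprocity", {
  expect_equal(rcv(0, 0), list(increase_pct = 100, decrease_pct = 100))
  r1 <- rcv_from_cv(51.0, 7.4)
  expect_equal(round(r1$increase_pct), 385)
  expect_equal(round(r1$decrease_pct), 26)
  r2 <- rcv_from_cv(38.2, 7.4)
  expect_equal(round(r2$increase_pct), 284)
  expect_equal(round(r2$decrease_pct), 35)
  expect_error(rcv(-0.1, 0.01), "non-negative")
  # multiplicative symmetry for arbitrary variances and z
  withr::with_seed(41, for (i in 1:25) {
    r <- rcv(runif(1, 0, 0.5), runif(1, 0, 0.1), z = runif(1, 0.5, 3))
    expect_equal(r$increase_pct * r$decrease_pct, 1e4, tolerance = 1e-9)
  })
})

test_that("RCV thresholds convert percentages into analyte bounds", {
  thr <- rcv_threshold(2, rcv_from_cv(48.7, 6.6))
  expect_equal(round(thr[["increase"]], 1), 7.3)
  thr14 <- rcv_threshold(2, rcv_from_cv(48.7, 14))
  expect_equal(round(thr14[["increase"]], 1), 7.6)
  expect_equal(rcv_threshold(1, rcv(0, 0)),
               c(decrease = 1, increase = 1))
  # accepts a full indices object too
  ind <- biovar_indices(generate_biovar_series(seed = 1))
  thr2 <- rcv_threshold(2, ind)
  expect_equal(thr2[["increase"]], 2 * ind$rcv_increase_pct / 100)
})

test_that("negative components are floored only at the reporting stage", {
  # tiny between-cat variation often drives the unbounded estimate negative
  found <- FALSE
  for (b in 1:30) {
    s <- generate_biovar_series(n_cats = 4, n_occasions = 3, cv_g = 1,
                                cv_i = 40, cv_a = 8, seed = 600 + b)
    f <- fit_nested_reml(s)
    if (f$sd2_G < 0) {
      found <- TRUE
      expect_warning(ind <- biovar_indices(f), "floored")
      expect_equal(unname(ind$cv_G["est"]), 0)
      expect_gte(ind$rcv_increase_pct, 100)
      break
    }
  }
  expect_true(found)     # the unbounded fit does produce negative estimates
})
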