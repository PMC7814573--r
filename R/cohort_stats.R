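#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided Wilcoxon (Mann-Whitney) rank-sum test with the descriptive
#' block conventional for clinical tables: mean, SD, median and type-7
#' quartiles per group. P-values come from exact enumeration when the
#' smaller group has at most `exact_max` observations and the pooled data
#' are tie-free; otherwise from the normal approximation with midranks,
#' tie-corrected variance and continuity correction.
#'
#' @param x,y Numeric samples for the two groups.
#' @param exact_max Largest min(n1, n2) for which the exact distribution
#'   is used.
#' @return Object of class `group_comparison` with `n1`, `n2`, per-group
#'   descriptives, `rank_sum_statistic` (rank sum of `x` in the pooled
#'   sample), `p_two_sided` and `method`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_two_sided  # 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12) {
  stopifnot(is.numeric(x), is.numeric(y))
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  rank_sum_x <- sum(ranks[seq_along(x)])
  desc <- function(v) list(n = length(v), mean = mean(v), sd = stats::sd(v),
                           median = stats::median(v),
                           q1 = stats::quantile(v, 0.25, type = 7,
                                                names = FALSE),
                           q3 = stats::quantile(v, 0.75, type = 7,
                                                names = FALSE))
  if (length(unique(pooled)) == 1) {
    warning("all values identical in both groups; p set to 1",
            call. = FALSE)
    p <- 1; method <- "degenerate"
  } else {
    ties <- anyDuplicated(pooled) > 0
    exact <- !ties && min(length(x), length(y)) <= exact_max
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE))
    p <- min(wt$p.value, 1)
    method <- if (exact) "exact" else "normal_approx_tie_corrected"
  }
  structure(list(n1 = length(x), n2 = length(y),
                 group1 = desc(x), group2 = desc(y),
                 rank_sum_statistic = rank_sum_x,
                 p_two_sided = p, method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  row <- function(g, lab)
    cat(sprintf("  %s: n=%d mean %.2f (SD %.2f), median %.2f (%.2f, %.2f)\n",
                lab, g$n, g$mean, g$sd, g$median, g$q1, g$q3))
  cat("Wilcoxon rank-sum comparison\n")
  row(x$group1, "group 1"); row(x$group2, "group 2")
  cat(sprintf("  rank sum (group 1) = %.1f, p = %.4g [%s]\n",
              x$rank_sum_statistic, x$p_two_sided, x$method))
  invisible(x)
}

#' Power or detectable effect for the rank-sum test (Noether)
#'
#' Noether's large-sample relation for the Wilcoxon rank-sum test links
#' total sample size `N`, the allocation fraction `c = n1/N`, the
#' two-sided significance level, the power, and the stochastic
#' superiority `p'' = P(X < Y)`:
#' `N = (z_{1-alpha/2} + z_power)^2 / (12 c (1-c) (p'' - 1/2)^2)`.
#' Supply exactly one of `power` / `p_doubleprime`; the other is solved
#' for. Power is evaluated with both rejection tails, so it approaches
#' `alpha` (not zero) as `p''` approaches one half.
#'
#' @param n1,n2 Group sizes.
#' @param alpha Two-sided significance level.
#' @param power Target power (supply this to solve for `p''`).
#' @param p_doubleprime P(X < Y) in (0.5, 1) (supply this to solve for
#'   power).
#' @return List with `n1`, `n2`, `alpha`, `power`, `p_doubleprime`, and
#'   `solved_for`.
#' @examples
#' noether(73, 77, power = 0.80)$p_doubleprime  # about 0.63
#' @export
noether <- function(n1, n2, alpha = 0.05, power = NULL,
                    p_doubleprime = NULL) {
  stopifnot(n1 >= 2, n2 >= 2, alpha > 0, alpha < 1)
  if (is.null(power) == is.null(p_doubleprime))
    stop("supply exactly one of power / p_doubleprime", call. = FALSE)
  N <- n1 + n2
  cc <- n1 / N
  za <- stats::qnorm(1 - alpha / 2)
  scale <- sqrt(12 * cc * (1 - cc) * N)
  if (is.null(p_doubleprime)) {
    stopifnot(power > 0, power < 1)
    zp <- stats::qnorm(power)
    p_doubleprime <- 0.5 + (za + zp) / scale
    solved <- "p_doubleprime"
  } else {
    if (p_doubleprime <= 0.5 || p_doubleprime >= 1)
      stop("p_doubleprime must lie in (0.5, 1)", call. = FALSE)
    solved <- "power"
  }
  delta <- scale * (p_doubleprime - 0.5)
  power <- stats::pnorm(delta - za) + stats::pnorm(-delta - za)
  list(n1 = n1, n2 = n2, alpha = alpha, power = power,
       p_doubleprime = p_doubleprime, solved_for = solved)
}

#' Ln-linear regression of an analyte on a predictor
#'
#' Ordinary least squares of `ln(response)` on a predictor (typically
#' body fat percentage), the model used when analyte residuals are
#' right-skewed on the natural scale. The slope `beta` is a proportional
#' effect: a `delta`-unit increase of the predictor multiplies the
#' analyte by `exp(beta * delta)`. The report includes the
#' percent change per 10 predictor units and residual normality
#' diagnostics (skewness, excess kurtosis, Shapiro-Wilk p for n <= 5000).
#'
#' @param response Strictly positive analyte values.
#' @param predictor Numeric predictor of the same length.
#' @param covariate Optional additional binary/numeric covariate, fitted
#'   additively; its p-value is reported alongside.
#' @return Object of class `ln_regression`: `beta`, `intercept`,
#'   `r_squared`, `p_value`, `pct_change_per_10`, `covariate_p`,
#'   `residual_diagnostics`, and the underlying `lm` fit.
#' @examples
#' b <- ln_regression(exp(0.0262 * (20:60)), 20:60)
#' b$beta
#' @export
ln_regression <- function(response, predictor, covariate = NULL) {
  stopifnot(is.numeric(response), is.numeric(predictor),
            length(response) == length(predictor))
  if (length(response) < 3) stop("need at least 3 observations",
                                 call. = FALSE)
  if (any(response <= 0)) stop("response must be strictly positive",
                               call. = FALSE)
  if (stats::var(predictor) == 0)
    stop("predictor has zero variance", call. = FALSE)
  ly <- log(response)
  dat <- data.frame(ly = ly, predictor = predictor)
  fml <- ly ~ predictor
  if (!is.null(covariate)) {
    dat$covariate <- covariate
    fml <- ly ~ predictor + covariate
  }
  fit <- stats::lm(fml, data = dat)
  sm <- summary(fit)
  beta <- unname(stats::coef(fit)["predictor"])
  res <- stats::residuals(fit)
  n <- length(res)
  m2 <- mean(res^2); m3 <- mean(res^3); m4 <- mean(res^4)
  diag <- list(
    skewness = m3 / m2^1.5,
    excess_kurtosis = m4 / m2^2 - 3,
    shapiro_p = if (n >= 3 && n <= 5000)
      stats::shapiro.test(res)$p.value else NA_real_)
  structure(
    list(beta = beta,
         intercept = unname(stats::coef(fit)["(Intercept)"]),
         r_squared = sm$r.squared,
         p_value = sm$coefficients["predictor", "Pr(>|t|)"],
         pct_change_per_10 = pct_change_per_delta(beta, 10),
         covariate_p = if (is.null(covariate)) NA_real_
                       else sm$coefficients["covariate", "Pr(>|t|)"],
         residual_diagnostics = diag,
         fit = fit),
    class = "ln_regression")
}

#' @export
print.ln_regression <- function(x, ...) {
  cat("Regression of ln(response) on predictor\n")
  cat(sprintf("  beta = %.4f  R^2 = %.3f  p = %.4g\n",
              x$beta, x$r_squared, x$p_value))
  cat(sprintf("  %+.1f%% change per 10 predictor units\n",
              x$pct_change_per_10))
  invisible(x)
}

#' Percent change implied by an ln-scale slope
#'
#' For a regression of `ln(analyte)` on a predictor, a slope `beta`
#' means a `delta`-unit predictor increase multiplies the analyte by
#' `exp(beta * delta)`, i.e. changes it by
#' `100 * (exp(beta * delta) - 1)` percent.
#'
#' @param beta Slope on the ln scale, per predictor unit.
#' @param delta Predictor change of interest.
#' @return Percent change.
#' @examples
#' pct_change_per_delta(0.0262, 10)  # about 30
#' @export
pct_change_per_delta <- function(beta, delta) {
  stopifnot(is.numeric(beta), is.numeric(delta))
  100 * (exp(beta * delta) - 1)
}

#' Group summary of a cohort in clinical-table shape
#'
#' Descriptive statistics and rank-sum comparisons of HOMA-IR, insulin
#' and glucose between the lean and overweight body-condition classes.
#'
#' @param cohort A `cat_cohort`.
#' @return A tibble with one row per analyte: group sizes, means, SDs,
#'   medians, quartiles and the two-sided rank-sum p-value.
#' @examples
#' cohort_summary(generate_cohort(n = 80, seed = 2))
#' @export
cohort_summary <- function(cohort) {
  df <- as.data.frame(cohort)
  cls <- classify_bcs(df$bcs_value, df$bcs_scale)
  homa <- homa_ir(df$insulin_mUL, df$glucose_mmolL)
  analytes <- list(homa_ir = homa, insulin_mUL = df$insulin_mUL,
                   glucose_mmolL = df$glucose_mmolL)
  rows <- lapply(names(analytes), function(nm) {
    v <- analytes[[nm]]
    cmp <- wilcoxon_rank_sum(v[cls == "lean"], v[cls == "overweight"])
    g1 <- cmp$group1; g2 <- cmp$group2
    tibble::tibble(
      analyte = nm, n_lean = g1$n, n_overweight = g2$n,
      lean_mean = g1$mean, lean_sd = g1$sd, lean_median = g1$median,
      lean_q1 = g1$q1, lean_q3 = g1$q3,
      over_mean = g2$mean, over_sd = g2$sd, over_median = g2$median,
      over_q1 = g2$q1, over_q3 = g2$q3,
      p_value = cmp$p_two_sided, method = cmp$method)
  })
  do.call(rbind, rows)
}
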