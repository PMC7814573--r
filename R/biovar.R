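#' Repeated-measures series for biological-variation analysis
#'
#' A long-format table of analyte values measured on several cats, on
#' several sampling occasions per cat, with (possibly) duplicate analytical
#' replicates per occasion. Values must be strictly positive because all
#' variance components are estimated on the natural-log scale. The design
#' may be unbalanced: missing replicates or occasions are allowed.
#'
#' @param cat_id Identifier of the animal.
#' @param occasion Sampling occasion index within cat.
#' @param replicate Analytical replicate index within occasion.
#' @param value Measured analyte value, strictly positive.
#' @param analyte Optional analyte label.
#' @param units Optional unit label.
#' @return A tibble of class `biovar_series`.
#' @export
biovar_series <- function(cat_id, occasion, replicate, value,
                          analyte = "", units = "") {
  stopifnot(is.numeric(value))
  if (any(!is.finite(value) | value <= 0))
    stop("analyte values must be strictly positive (ln transform)",
         call. = FALSE)
  x <- tibble::tibble(cat_id = as.character(cat_id),
                      occasion = as.integer(occasion),
                      replicate = as.integer(replicate),
                      value = as.numeric(value))
  if (anyDuplicated(x[c("cat_id", "occasion", "replicate")]))
    stop("duplicate (cat, occasion, replicate) entries", call. = FALSE)
  if (length(unique(x$cat_id)) < 2)
    stop("need at least 2 cats", call. = FALSE)
  if (max(table(x$cat_id[!duplicated(paste(x$cat_id, x$occasion))])) < 2)
    stop("need at least 2 occasions for at least one cat", call. = FALSE)
  structure(x, analyte = analyte, units = units,
            class = c("biovar_series", class(x)))
}

# -- restricted log-likelihood machinery --------------------------------

# Balanced complete design: I cats x J occasions x K replicates. The
# covariance eigenvalues are lam1 = sA, lam2 = sA + K sI,
# lam3 = sA + K sI + J K sG, and the restricted likelihood reduces to the
# three nested sums of squares, making each evaluation O(1).
balanced_reml_nll <- function(ss, I, J, K) {
  function(th) {
    sG <- th[1]; sI <- th[2]; sA <- th[3]
    lam1 <- sA
    lam2 <- sA + K * sI
    lam3 <- sA + K * sI + J * K * sG
    if ((K > 1 && lam1 <= 0) || lam2 <= 0 || lam3 <= 0) return(1e10)
    val <- I * (J - 1) * log(lam2) + I * log(lam3) +
      log(I * J * K / lam3) +
      K * ss$occ / lam2 + J * K * ss$cat / lam3
    if (K > 1) val <- val + I * J * (K - 1) * log(lam1) + ss$rep / lam1
    0.5 * val
  }
}

# General (unbalanced) design: the marginal covariance is block-diagonal
# by cat, so determinants and quadratic forms are accumulated per cat.
dense_reml_nll <- function(blocks) {
  function(th) {
    sG <- th[1]; sI <- th[2]; sA <- th[3]
    logdet <- 0; s11 <- 0; s1y <- 0; syy <- 0
    for (b in blocks) {
      V <- sA * diag(b$n) + sI * b$B + sG
      R <- tryCatch(suppressWarnings(chol(V)), error = function(e) NULL)
      if (is.null(R) || any(diag(R) < 1e-12)) return(1e10)
      u1 <- backsolve(R, forwardsolve(t(R), rep(1, b$n)))
      uy <- backsolve(R, forwardsolve(t(R), b$y))
      logdet <- logdet + 2 * sum(log(diag(R)))
      s11 <- s11 + sum(u1)
      s1y <- s1y + sum(b$y * u1)
      syy <- syy + sum(b$y * uy)
    }
    if (s11 <= 0) return(1e10)
    0.5 * (logdet + log(s11) + syy - s1y^2 / s11)
  }
}

# Closed-form nested-ANOVA estimators; exact REML solution on balanced
# complete designs, a starting value otherwise.
nested_anova_estimates <- function(y, cat, occf) {
  n <- length(y)
  occ_mean <- tapply(y, occf, mean)
  occ_n <- tapply(y, occf, length)
  occ_cat <- tapply(as.character(cat), occf, `[`, 1)
  cat_mean <- tapply(occ_mean, occ_cat, mean)   # mean of occasion means
  ss_rep <- sum((y - occ_mean[occf])^2)
  df_rep <- n - nlevels(occf)
  ss_occ <- sum((occ_mean - cat_mean[occ_cat])^2)
  df_occ <- nlevels(occf) - length(cat_mean)
  ss_cat <- sum((cat_mean - mean(cat_mean))^2)
  kbar <- mean(occ_n)
  jbar <- nlevels(occf) / length(cat_mean)
  sA <- if (df_rep > 0) ss_rep / df_rep else 0
  sI <- if (df_occ > 0) ss_occ / df_occ - sA / kbar else 0
  sG <- ss_cat / max(length(cat_mean) - 1, 1) - sI / jbar - sA / (jbar * kbar)
  c(sG = sG, sI = sI, sA = sA)
}

#' Fit nested random-effects variance components by unbounded REML
#'
#' Fits the two-level nested Gaussian model on the natural-log scale,
#' `ln y = mu + cat + occasion(cat) + replicate error`, by direct
#' maximisation of the restricted log-likelihood. Estimation is
#' *unbounded*: variance components may go negative as long as the
#' implied marginal covariance stays positive definite, matching the
#' behaviour of mixed-model software that does not constrain components.
#' On balanced complete designs the optimum coincides with the classical
#' nested-ANOVA mean-square estimators, which are used as the starting
#' point (and, on balanced data, verified against the optimiser).
#'
#' The three components are, on the ln scale: `sd2_G` between cats,
#' `sd2_I` within cat between occasions, and `sd2_A` between analytical
#' duplicates. `sd2_A` requires duplicate replicates somewhere in the
#' design; without any duplicates a two-component model is fitted and
#' `sd2_A` is reported as `NA`.
#'
#' @param series A [biovar_series()] (or data frame with the same
#'   columns). Values are ln-transformed internally.
#' @param screen_outliers If `TRUE`, occasions whose duplicate ln
#'   difference falls outside Tukey fences are dropped before fitting
#'   (off by default; the screen is always reported via a message).
#' @return An object of class `variance_components`: the three ln-scale
#'   components, `converged`, the restricted log-likelihood, the
#'   asymptotic covariance of the components (from the curvature of the
#'   restricted likelihood; `NULL` when singular), and design counts.
#' @examples
#' s <- generate_biovar_series(seed = 1)
#' fit_nested_reml(s)
#' @export
fit_nested_reml <- function(series, screen_outliers = FALSE) {
  df <- as.data.frame(series)
  stopifnot(all(c("cat_id", "occasion", "value") %in% names(df)))
  if (any(df$value <= 0)) stop("values must be strictly positive",
                               call. = FALSE)
  if (length(unique(df$cat_id)) < 2 || length(unique(df$occasion)) < 2)
    stop("design error: need >= 2 cats and >= 2 occasions", call. = FALSE)

  if (screen_outliers) df <- screen_duplicate_outliers(df)

  y <- log(df$value)
  cat <- factor(df$cat_id)
  occf <- factor(paste(df$cat_id, df$occasion, sep = "\r"))
  n <- length(y)
  occ_per_cat <- table(cat[!duplicated(occf)])
  reps_per_occ <- table(occf)
  has_dup <- any(reps_per_occ >= 2)

  out <- list(sd2_G = 0, sd2_I = 0, sd2_A = if (has_dup) 0 else NA_real_,
              converged = TRUE, log_restricted_likelihood = NA_real_,
              vcov = NULL, n_cats = nlevels(cat),
              n_occasions = as.integer(max(occ_per_cat)),
              n_obs = n, has_duplicates = has_dup,
              analyte = attr(series, "analyte") %||% "")
  class(out) <- "variance_components"
  if (stats::var(y) == 0) {                       # degenerate: no variance
    out$vcov <- matrix(0, 3, 3,
                       dimnames = list(c("G", "I", "A"), c("G", "I", "A")))
    return(out)
  }

  balanced <- length(unique(occ_per_cat)) == 1 &&
    length(unique(reps_per_occ)) == 1 && min(occ_per_cat) >= 2
  start <- nested_anova_estimates(y, cat, occf)

  if (!has_dup) {
    # no duplicates anywhere: sd2_A is confounded with sd2_I; fit the
    # two-component model with the analytical term fixed at zero
    nll3 <- make_nll(y, cat, occf, balanced)
    nll <- function(th2) nll3(c(th2[1], th2[2], 0))
    start2 <- c(start[["sG"]], start[["sI"]] + start[["sA"]])
    opt <- reml_optimise(nll, start2)
    out$sd2_G <- opt$par[1]; out$sd2_I <- opt$par[2]
    out$converged <- opt$converged
    out$log_restricted_likelihood <- -(opt$value + (n - 1) / 2 * log(2 * pi))
    out$vcov <- reml_vcov(nll, opt$par, c("G", "I"))
    return(out)
  }

  nll <- make_nll(y, cat, occf, balanced)
  opt <- reml_optimise(nll, start)
  out$sd2_G <- opt$par[1]; out$sd2_I <- opt$par[2]; out$sd2_A <- opt$par[3]
  out$converged <- opt$converged
  out$log_restricted_likelihood <- -(opt$value + (n - 1) / 2 * log(2 * pi))
  out$vcov <- reml_vcov(nll, opt$par, c("G", "I", "A"))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_nll <- function(y, cat, occf, balanced) {
  if (balanced) {
    occ_mean <- tapply(y, occf, mean)
    occ_cat <- tapply(as.character(cat), occf, `[`, 1)
    cat_mean <- tapply(occ_mean, occ_cat, mean)
    ss <- list(rep = sum((y - occ_mean[occf])^2),
               occ = sum((occ_mean - cat_mean[occ_cat])^2),
               cat = sum((cat_mean - mean(cat_mean))^2))
    I <- nlevels(cat)
    J <- nlevels(occf) / I
    K <- length(y) / nlevels(occf)
    balanced_reml_nll(ss, I, J, K)
  } else {
    idx <- split(seq_along(y), cat)
    blocks <- lapply(idx, function(i) {
      o <- factor(as.character(occf[i]))
      Z <- stats::model.matrix(~ 0 + o)
      list(y = y[i], B = tcrossprod(Z), n = length(i))
    })
    dense_reml_nll(blocks)
  }
}

reml_optimise <- function(nll, start) {
  o1 <- stats::optim(start, nll, method = "Nelder-Mead",
                     control = list(maxit = 5000, reltol = 1e-14))
  o2 <- stats::optim(o1$par, nll, method = "Nelder-Mead",
                     control = list(maxit = 5000, reltol = 1e-14))
  cand <- list(start = start, o1 = o1$par, o2 = o2$par)
  vals <- vapply(cand, nll, numeric(1))
  best <- which.min(vals)
  list(par = unname(cand[[best]]), value = unname(vals[best]),
       converged = o2$convergence == 0 && vals[best] < 1e9)
}

reml_vcov <- function(nll, par, names) {
  H <- tryCatch(stats::optimHess(par, nll), error = function(e) NULL)
  if (is.null(H)) return(NULL)
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(V)) || any(diag(V) < 0)) return(NULL)
  dimnames(V) <- list(names, names)
  V
}

# Tukey-fence screen on ln duplicate differences; drops whole occasions
# whose duplicate disagreement is an outlier. Always reports what it did.
screen_duplicate_outliers <- function(df) {
  occ <- interaction(df$cat_id, df$occasion, drop = TRUE)
  d <- tapply(log(df$value), occ, function(v)
    if (length(v) >= 2) diff(range(v)) else NA_real_)
  d_ok <- d[!is.na(d)]
  if (length(d_ok) < 4) return(df)
  q <- stats::quantile(d_ok, c(0.25, 0.75), type = 7)
  fence <- q[2] + 1.5 * diff(q)
  bad <- names(d_ok)[d_ok > fence]
  message(sprintf("duplicate outlier screen: %d occasion(s) dropped", length(bad)))
  df[!occ %in% bad, , drop = FALSE]
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Nested variance components (ln scale, unbounded REML)\n")
  cat(sprintf("  cats: %d  occasions: %d  observations: %d\n",
              x$n_cats, x$n_occasions, x$n_obs))
  cat(sprintf("  sd2_G = %.6g  sd2_I = %.6g  sd2_A = %s\n",
              x$sd2_G, x$sd2_I,
              if (is.na(x$sd2_A)) "NA (no duplicates)"
              else sprintf("%.6g", x$sd2_A)))
  cat(sprintf("  restricted logLik = %.4f  converged: %s\n",
              x$log_restricted_likelihood, x$converged))
  invisible(x)
}

# -- CV conversion, II and RCV ------------------------------------------

#' Coefficient of variation from an ln-scale standard deviation
#'
#' Cole's exact relation between the standard deviation of `ln x` and the
#' coefficient of variation of `x` for lognormal data:
#' `CV = sqrt(exp(SD^2(ln x)) - 1)`, returned as a percentage. For small
#' `sd_ln` this approaches `100 * sd_ln`.
#'
#' @param sd_ln Standard deviation of the ln-transformed analyte
#'   (non-negative; floor negative variance components upstream).
#' @return CV in percent.
#' @examples
#' cv_from_sdln(0.48086)  # about 51
#' @export
cv_from_sdln <- function(sd_ln) {
  stopifnot(is.numeric(sd_ln))
  if (any(sd_ln < 0, na.rm = TRUE))
    stop("sd_ln must be non-negative; floor negative components first",
         call. = FALSE)
  100 * sqrt(exp(sd_ln^2) - 1)
}

#' Invert Cole's equation: ln-scale SD from a CV
#'
#' @param cv_pct Coefficient of variation in percent (non-negative).
#' @return Standard deviation on the ln scale.
#' @export
sdln_from_cv <- function(cv_pct) {
  stopifnot(is.numeric(cv_pct))
  if (any(cv_pct < 0, na.rm = TRUE))
    stop("cv_pct must be non-negative", call. = FALSE)
  sqrt(log1p((cv_pct / 100)^2))
}

#' Wald confidence intervals for variance components, expressed as CVs
#'
#' Builds `estimate +/- z * SE` intervals on the ln-variance scale from
#' the curvature of the restricted likelihood, sets negative lower limits
#' to zero, and maps every endpoint through Cole's equation so the
#' interval is reported as a CV in percent.
#'
#' @param fit A `variance_components` object from [fit_nested_reml()].
#' @param z Standard-normal quantile (default 1.96 for 95% intervals).
#' @return A tibble with one row per component (G, I, A): variance,
#'   standard error, variance-scale CI, and the CV with its CI. When the
#'   information matrix is singular the intervals are `NA` and the
#'   attribute `ci_available` is `FALSE`.
#' @export
wald_ci_components <- function(fit, z = 1.96) {
  stopifnot(inherits(fit, "variance_components"))
  if (!fit$converged)
    warning("fit did not converge; intervals are unreliable", call. = FALSE)
  comp <- c(G = fit$sd2_G, I = fit$sd2_I, A = fit$sd2_A)
  se <- rep(NA_real_, 3); names(se) <- names(comp)
  ok <- !is.null(fit$vcov)
  if (ok) {
    d <- sqrt(diag(fit$vcov))
    se[names(d)] <- d
  }
  lo <- comp - z * se
  hi <- comp + z * se
  to_cv <- function(v) ifelse(is.na(v), NA_real_,
                              cv_from_sdln(sqrt(pmax(v, 0))))
  if (any(comp < 0, na.rm = TRUE))
    warning("negative variance component(s) floored to zero for CV",
            call. = FALSE)
  out <- tibble::tibble(
    component = names(comp),
    variance = unname(comp),
    se = unname(se),
    var_lower = unname(pmax(lo, 0)),
    var_upper = unname(hi),
    cv = to_cv(unname(comp)),
    cv_lower = to_cv(unname(pmax(lo, 0))),
    cv_upper = to_cv(unname(hi)))
  attr(out, "ci_available") <- ok
  out
}

#' Index of individuality
#'
#' `II = CV_G / sqrt(CV_I^2 + CV_A^2)`. Values below 0.7 indicate low
#' individuality (population-based reference intervals are adequate);
#' values above 1.7 indicate high individuality (serial monitoring with
#' reference change values is preferable).
#'
#' @param cv_G,cv_I,cv_A Between-subject, within-subject and analytical
#'   CVs, in percent.
#' @return The index (unitless, non-negative).
#' @examples
#' index_of_individuality(52.3, 51.0, 7.4)  # about 1.01
#' @export
index_of_individuality <- function(cv_G, cv_I, cv_A) {
  stopifnot(is.numeric(cv_G), is.numeric(cv_I), is.numeric(cv_A))
  if (any(c(cv_G, cv_I, cv_A) < 0))
    stop("CVs must be non-negative", call. = FALSE)
  denom <- sqrt(cv_I^2 + cv_A^2)
  if (any(denom == 0))
    stop("CV_I and CV_A cannot both be zero", call. = FALSE)
  cv_G / denom
}

#' Reference change value for ln-normal analytes
#'
#' Two-sided RCV on the natural scale for an analyte analysed on the ln
#' scale: `100 * exp(+/- z * sqrt(2 * (SD_I^2(ln x) + SD_A^2(ln x))))`.
#' Back-transforming makes the bounds asymmetric: the significant
#' increase exceeds 100% by more than the significant decrease falls
#' below it, and `increase * decrease = 100^2` exactly.
#'
#' @param sd2_I_ln Within-subject variance on the ln scale.
#' @param sd2_A_ln Analytical variance on the ln scale.
#' @param z Standard-normal quantile (1.96 for 95% two-sided probability).
#' @return List with `increase_pct` and `decrease_pct`: a second result
#'   above `increase_pct` % of baseline, or below `decrease_pct` %, is a
#'   significant change.
#' @examples
#' rcv_from_cv(51.0, 7.4)  # increase ~385%, decrease ~26%
#' @export
rcv <- function(sd2_I_ln, sd2_A_ln, z = 1.96) {
  stopifnot(is.numeric(sd2_I_ln), is.numeric(sd2_A_ln), z > 0)
  if (any(c(sd2_I_ln, sd2_A_ln) < 0))
    stop("variances must be non-negative; floor upstream", call. = FALSE)
  d <- sqrt(2 * (sd2_I_ln + sd2_A_ln))
  list(increase_pct = 100 * exp(z * d), decrease_pct = 100 * exp(-z * d))
}

#' @rdname rcv
#' @param cv_I_pct,cv_A_pct Within-subject and analytical CVs in percent,
#'   converted to ln-variances by inverting Cole's equation.
#' @export
rcv_from_cv <- function(cv_I_pct, cv_A_pct, z = 1.96) {
  rcv(sdln_from_cv(cv_I_pct)^2, sdln_from_cv(cv_A_pct)^2, z)
}

#' Per-individual significant-change thresholds from a baseline
#'
#' Converts RCV percentages into absolute analyte bounds for a given
#' baseline concentration: a second measurement above the upper bound or
#' below the lower bound is a significant change for that individual.
#'
#' @param baseline Baseline concentration, strictly positive.
#' @param indices A [biovar_indices()] object, an [rcv()] result, or any
#'   list with `rcv_increase_pct`/`rcv_decrease_pct` or
#'   `increase_pct`/`decrease_pct` elements.
#' @return Named numeric vector `c(decrease = ..., increase = ...)` in the
#'   analyte's units.
#' @examples
#' rcv_threshold(2, rcv_from_cv(48.7, 6.6))["increase"]  # ~7.3 mU/L
#' @export
rcv_threshold <- function(baseline, indices) {
  stopifnot(is.numeric(baseline), all(baseline > 0))
  inc <- indices$rcv_increase_pct %||% indices$increase_pct
  dec <- indices$rcv_decrease_pct %||% indices$decrease_pct
  if (is.null(inc) || is.null(dec))
    stop("indices must carry RCV increase/decrease percentages",
         call. = FALSE)
  c(decrease = baseline * dec / 100, increase = baseline * inc / 100)
}

#' Full set of biological-variation indices
#'
#' Fits (or accepts) the nested REML model and derives the standard
#' biological-variation report: the three CVs with 95% Wald confidence
#' intervals (negative lower limits set to zero), the index of
#' individuality, and the asymmetric reference change values. Negative
#' variance point estimates are floored to zero, with a warning, only at
#' this conversion step — the unbounded fit itself is left untouched.
#'
#' @param x A [biovar_series()] or a fitted `variance_components` object.
#' @param z Standard-normal quantile for both the Wald CIs and the RCV.
#' @param ... Passed to [fit_nested_reml()] when `x` is a series.
#' @return An object of class `biovar_indices` with elements `cv_G`,
#'   `cv_I`, `cv_A` (each `c(est, lower, upper)` in percent), `ii`,
#'   `rcv_increase_pct`, `rcv_decrease_pct`, `z`, `n_cats`,
#'   `n_occasions`, and the underlying `fit`.
#' @examples
#' biovar_indices(generate_biovar_series(seed = 42))
#' @export
biovar_indices <- function(x, z = 1.96, ...) {
  fit <- if (inherits(x, "variance_components")) x else fit_nested_reml(x, ...)
  if (is.na(fit$sd2_A))
    stop("analytical component not estimable (no duplicate replicates)",
         call. = FALSE)
  ci <- suppressWarnings(wald_ci_components(fit, z = z))
  if (any(c(fit$sd2_G, fit$sd2_I, fit$sd2_A) < 0))
    warning("negative variance component(s) floored to zero for indices",
            call. = FALSE)
  v <- pmax(c(G = fit$sd2_G, I = fit$sd2_I, A = fit$sd2_A), 0)
  cvs <- cv_from_sdln(sqrt(v))
  pick <- function(k) {
    r <- ci[ci$component == k, ]
    c(est = cv_from_sdln(sqrt(max(r$variance, 0))),
      lower = r$cv_lower, upper = r$cv_upper)
  }
  r <- rcv(v[["I"]], v[["A"]], z = z)
  structure(
    list(cv_G = pick("G"), cv_I = pick("I"), cv_A = pick("A"),
         ii = index_of_individuality(cvs[["G"]], cvs[["I"]], cvs[["A"]]),
         rcv_increase_pct = r$increase_pct,
         rcv_decrease_pct = r$decrease_pct,
         z = z, n_cats = fit$n_cats, n_occasions = fit$n_occasions,
         analyte = fit$analyte, fit = fit),
    class = "biovar_indices")
}

#' @export
print.biovar_indices <- function(x, ...) {
  fmt <- function(v) sprintf("%.1f (%.1f-%.1f)", v["est"], v["lower"],
                             v["upper"])
  cat(sprintf("Biological variation%s: %d cats, %d occasions\n",
              if (nzchar(x$analyte)) paste0(" of ", x$analyte) else "",
              x$n_cats, x$n_occasions))
  cat("  CV_G % (95% CI):", fmt(x$cv_G), "\n")
  cat("  CV_I % (95% CI):", fmt(x$cv_I), "\n")
  cat("  CV_A % (95% CI):", fmt(x$cv_A), "\n")
  cat(sprintf("  II: %.2f\n", x$ii))
  cat(sprintf("  RCV increase: %.0f%%   decrease: %.0f%%\n",
              x$rcv_increase_pct, x$rcv_decrease_pct))
  invisible(x)
}
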