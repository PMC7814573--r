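#' Generate a synthetic feline cohort
#'
#' Emulates the statistical structure of a clinical feline obesity
#' cohort: body fat percentage drawn from a truncated normal
#' (mean 38.0, SD 11.9, range 15.3-61.9 before truncation adjustment);
#' ln(insulin) linear in BF% with slope `beta_insulin` plus Gaussian
#' noise; ln(glucose) linear in BF% with the residual slope
#' `beta_homa - beta_insulin`, so that HOMA-IR — always derived exactly
#' as insulin x glucose / 22.5 — carries the target ln-scale slope
#' `beta_homa` on BF%. Body condition scores are assigned from the true
#' BF% class and then corrupted at the configured misclassification
#' rates, reproducing in expectation the predictive values of BCS
#' against BF%. Clinical flags (stress at sampling, suspected diabetes
#' with raised fructosamine, stress hyperglycemia with normal
#' fructosamine, insulin assay interference) are planted in
#' deterministically rounded numbers of cats.
#'
#' The noise standard deviations default to values giving the observed
#' explanatory power of body fat (about R^2 0.13-0.15 for insulin and
#' HOMA-IR, 0.03-0.05 for glucose) at the default BF% spread.
#'
#' @param n Number of cats.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param bf_mean,bf_sd,bf_range Body-fat distribution (truncated-normal
#'   rejection sampling inside `bf_range`).
#' @param beta_insulin,beta_homa Target ln-scale slopes of insulin and
#'   HOMA-IR on BF%, per BF% unit.
#' @param insulin_median,glucose_median Analyte medians at `bf_mean`.
#' @param noise_sd_ln_insulin,noise_sd_ln_glucose Residual SDs on the ln
#'   scale.
#' @param p_lean_wrong Probability a truly lean (BF% < 35) cat is scored
#'   overweight by BCS.
#' @param p_over_wrong Probability a truly overweight/obese cat is scored
#'   lean by BCS.
#' @param fraction_scale5 Fraction of cats scored on the 5-point scale.
#' @param fraction_stressed,fraction_interference,fraction_dm,fraction_stress_hyper
#'   Fractions of cats flagged stressed, with insulin assay interference,
#'   with hyperglycemia plus raised fructosamine (suspected diabetes),
#'   and with stress hyperglycemia (glucose 13 mmol/L, normal
#'   fructosamine). Counts are `round(fraction * n)` and the groups are
#'   disjoint.
#' @param fraction_locomotor Fraction with signs from the locomotor
#'   apparatus.
#' @param bf_missing_fraction Fraction of cats without CT body fat
#'   (`bf_percent` set `NA`).
#' @return A validated `cat_cohort` tibble.
#' @examples
#' cohort <- generate_cohort(n = 161, seed = 1)
#' nrow(cohort)
#' @export
generate_cohort <- function(n = 161,
                            seed = 1,
                            bf_mean = 38.0, bf_sd = 11.9,
                            bf_range = c(15.3, 61.9),
                            beta_insulin = 0.0225, beta_homa = 0.0262,
                            insulin_median = 5.0, glucose_median = 5.8,
                            noise_sd_ln_insulin = 0.60,
                            noise_sd_ln_glucose = 0.23,
                            p_lean_wrong = 0.5, p_over_wrong = 0.025,
                            fraction_scale5 = 20 / 150,
                            fraction_stressed = 9 / 161,
                            fraction_interference = 1 / 161,
                            fraction_dm = 1 / 161,
                            fraction_stress_hyper = 3 / 161,
                            fraction_locomotor = 33 / 150,
                            bf_missing_fraction = 0) {
  stopifnot(n >= 1, bf_sd > 0, bf_range[1] < bf_range[2],
            all(c(p_lean_wrong, p_over_wrong, fraction_scale5,
                  fraction_stressed, fraction_interference, fraction_dm,
                  fraction_stress_hyper, fraction_locomotor,
                  bf_missing_fraction) >= 0),
            all(c(p_lean_wrong, p_over_wrong) <= 1))
  beta_glucose <- beta_homa - beta_insulin
  withr::with_seed(seed, {
    bf <- rtrunc_norm(n, bf_mean, bf_sd, bf_range)
    insulin <- exp(log(insulin_median) + beta_insulin * (bf - bf_mean) +
                     stats::rnorm(n, 0, noise_sd_ln_insulin))
    glucose <- exp(log(glucose_median) + beta_glucose * (bf - bf_mean) +
                     stats::rnorm(n, 0, noise_sd_ln_glucose))
    fructosamine <- rep(NA_real_, n)

    # plant clinical special cases in disjoint, deterministically sized sets
    n_str <- round(fraction_stressed * n)
    n_int <- round(fraction_interference * n)
    n_dm <- round(fraction_dm * n)
    n_hyp <- round(fraction_stress_hyper * n)
    special <- sample.int(n, min(n, n_str + n_int + n_dm + n_hyp))
    i_str <- special[seq_len(n_str)]
    i_int <- special[n_str + seq_len(n_int)]
    i_dm <- special[n_str + n_int + seq_len(n_dm)]
    i_hyp <- special[n_str + n_int + n_dm + seq_len(n_hyp)]
    stressed <- seq_len(n) %in% i_str
    interference <- seq_len(n) %in% i_int
    glucose[i_dm] <- stats::runif(length(i_dm), 12, 18)
    fructosamine[i_dm] <- stats::runif(length(i_dm), 480, 650)
    glucose[i_hyp] <- 13
    fructosamine[i_hyp] <- stats::runif(length(i_hyp), 250, 340)
    insulin[i_int] <- stats::runif(length(i_int), 150, 400)

    # BCS from the true body-fat class, with misclassification
    lean_true <- bf < 35
    u <- stats::runif(n)
    bcs_lean <- ifelse(lean_true, u >= p_lean_wrong, u < p_over_wrong)
    scale5 <- stats::runif(n) < fraction_scale5
    bcs_value <- integer(n)
    n_l <- sum(bcs_lean); n_o <- n - n_l
    bcs_value[bcs_lean] <- sample(3:5, n_l, replace = TRUE,
                                  prob = c(0.02, 0.10, 0.88))
    bcs_value[!bcs_lean] <- sample(6:9, n_o, replace = TRUE,
                                   prob = c(0.46, 0.36, 0.14, 0.04))
    bcs_value[scale5 & bcs_lean] <- 3
    bcs_value[scale5 & !bcs_lean] <- sample(4:5, sum(scale5 & !bcs_lean),
                                            replace = TRUE,
                                            prob = c(0.9, 0.1))

    sex <- sample(c("male", "female"), n, replace = TRUE,
                  prob = c(72, 78) / 150)
    neutered <- ifelse(sex == "male", stats::runif(n) < 67 / 72,
                       stats::runif(n) < 55 / 78)
    breed <- sample(c("Domestic short/longhair", "Maine Coon", "Birman",
                      "Burmese", "British shorthair", "Other"),
                    n, replace = TRUE,
                    prob = c(53, 37, 23, 14, 5, 18) / 150)
    bf_out <- bf
    if (bf_missing_fraction > 0)
      bf_out[sample.int(n, round(bf_missing_fraction * n))] <- NA_real_

    tab <- tibble::tibble(
      cat_id = sprintf("cat%03d", seq_len(n)),
      age_years = rtrunc_norm(n, 7.1, 3.8, c(1, 20)),
      sex = sex, neutered = neutered, breed = breed,
      bcs_value = bcs_value,
      bcs_scale = ifelse(scale5, 5L, 9L),
      insulin_mUL = insulin, glucose_mmolL = glucose,
      fructosamine = fructosamine, bf_percent = bf_out,
      stressed = stressed,
      locomotor_signs = stats::runif(n) < fraction_locomotor,
      insulin_interference = interference,
      fasted = TRUE, pregnant = FALSE)
    validate_cohort(tab)
  })
}

# truncated-normal rejection sampler
rtrunc_norm <- function(n, mean, sd, range) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

#' Generate a repeated-measures biological-variation series
#'
#' Lognormal construction on three nested Gaussian effects:
#' `value = grand_mean * exp(g_cat + w_occasion + a_replicate)`, with the
#' effect SDs obtained from the target CVs by inverting Cole's equation
#' (`sd_ln = sqrt(ln(1 + (CV/100)^2))`). Defaults mirror a design of 7
#' cats sampled weekly for 5 weeks with duplicate analyses, at the
#' biological-variation level observed for feline HOMA-IR.
#'
#' @param n_cats,n_occasions,n_replicates Design dimensions.
#' @param cv_g,cv_i,cv_a Between-cat, within-cat and analytical CVs in
#'   percent.
#' @param grand_mean Multiplicative centre of the analyte (the median of
#'   the generated lognormal values).
#' @param drop_one_replicate If `TRUE`, removes one replicate from the
#'   first cat's first occasion, mimicking a lost duplicate.
#' @param analyte,units Labels carried on the series.
#' @param seed Integer seed.
#' @return A [biovar_series()].
#' @examples
#' s <- generate_biovar_series(seed = 1)
#' fit_nested_reml(s)$converged
#' @export
generate_biovar_series <- function(n_cats = 7, n_occasions = 5,
                                   n_replicates = 2,
                                   cv_g = 52.3, cv_i = 51.0, cv_a = 7.4,
                                   grand_mean = 0.78,
                                   drop_one_replicate = FALSE,
                                   analyte = "HOMA-IR", units = "",
                                   seed = 1) {
  stopifnot(n_cats >= 2, n_occasions >= 2, n_replicates >= 1,
            grand_mean > 0, cv_g >= 0, cv_i >= 0, cv_a >= 0)
  withr::with_seed(seed, {
    sg <- sdln_from_cv(cv_g); si <- sdln_from_cv(cv_i)
    sa <- sdln_from_cv(cv_a)
    g <- stats::rnorm(n_cats, 0, sg)
    w <- matrix(stats::rnorm(n_cats * n_occasions, 0, si),
                n_cats, n_occasions)
    idx <- expand.grid(replicate = seq_len(n_replicates),
                       occasion = seq_len(n_occasions),
                       cat = seq_len(n_cats))
    a <- stats::rnorm(nrow(idx), 0, sa)
    value <- grand_mean *
      exp(g[idx$cat] + w[cbind(idx$cat, idx$occasion)] + a)
    keep <- rep(TRUE, nrow(idx))
    if (drop_one_replicate && n_replicates >= 2)
      keep[idx$cat == 1 & idx$occasion == 1 &
             idx$replicate == n_replicates] <- FALSE
    biovar_series(cat_id = sprintf("cat%02d", idx$cat[keep]),
                  occasion = idx$occasion[keep],
                  replicate = idx$replicate[keep],
                  value = value[keep],
                  analyte = analyte, units = units)
  })
}

#' Generate a bimodal CT voxel phantom
#'
#' Two-component Gaussian mixture of integer HU values with an *exact*
#' mixing fraction (`round(fat_fraction * n)` fat voxels), emulating the
#' fat and lean soft-tissue attenuation peaks of a masked whole-body
#' feline CT. Optionally adds out-of-window contaminant voxels (uniform
#' in \[-600, -251\] and \[251, 600\]) to exercise windowing.
#'
#' @param n_voxels Total voxel count.
#' @param fat_fraction Fraction of in-window voxels that are fat.
#' @param fat_mode_hu,lean_mode_hu Mode positions (inside the window).
#' @param mode_sd_hu Common mode standard deviation; phantoms are
#'   valid-truth when the modes are at least 4 SD apart.
#' @param out_of_window_fraction Fraction of voxels planted outside the
#'   window.
#' @param seed Integer seed.
#' @return Integer-valued numeric vector of HU values, shuffled.
#' @examples
#' v <- generate_phantom(1e4, fat_fraction = 0.38, seed = 1)
#' body_fat(v)$bf_percent
#' @export
generate_phantom <- function(n_voxels = 1e6, fat_fraction = 0.38,
                             fat_mode_hu = -100, lean_mode_hu = 60,
                             mode_sd_hu = 20,
                             out_of_window_fraction = 0, seed = 1) {
  stopifnot(n_voxels >= 1, fat_fraction >= 0, fat_fraction <= 1,
            fat_mode_hu > -250, fat_mode_hu < 250,
            lean_mode_hu > -250, lean_mode_hu < 250,
            fat_mode_hu < lean_mode_hu, mode_sd_hu > 0,
            out_of_window_fraction >= 0, out_of_window_fraction < 1)
  withr::with_seed(seed, {
    n_out <- round(out_of_window_fraction * n_voxels)
    n_in <- n_voxels - n_out
    n_fat <- round(fat_fraction * n_in)
    fat <- stats::rnorm(n_fat, fat_mode_hu, mode_sd_hu)
    lean <- stats::rnorm(n_in - n_fat, lean_mode_hu, mode_sd_hu)
    side <- sample(c(-1, 1), n_out, replace = TRUE)
    out <- side * stats::runif(n_out, 251, 600)
    sample(round(c(fat, lean, out)))
  })
}
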