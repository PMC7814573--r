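#' Homeostasis model assessment of insulin resistance (HOMA-IR)
#'
#' HOMA-IR is the standard single-sample surrogate for insulin resistance:
#' fasting glucose (mmol/L) times fasting insulin (mU/L), divided by the
#' normalising constant 22.5. Higher values indicate reduced tissue
#' sensitivity to insulin.
#'
#' @param insulin_mUL Fasting serum insulin in mU/L; strictly positive.
#' @param glucose_mmolL Fasting glucose in mmol/L; strictly positive.
#'
#' @return A numeric vector of unitless HOMA-IR values. `NA` inputs
#'   propagate.
#' @examples
#' homa_ir(22.5, 1)      # 1
#' homa_ir(9.3, 6.3)     # 2.604
#' @export
homa_ir <- function(insulin_mUL, glucose_mmolL) {
  stopifnot(is.numeric(insulin_mUL), is.numeric(glucose_mmolL))
  if (any(insulin_mUL <= 0, na.rm = TRUE))
    stop("insulin must be strictly positive (mU/L)", call. = FALSE)
  if (any(glucose_mmolL <= 0, na.rm = TRUE))
    stop("glucose must be strictly positive (mmol/L)", call. = FALSE)
  insulin_mUL * glucose_mmolL / 22.5
}

#' Convert insulin from ng/L to mU/L
#'
#' Feline insulin ELISA results reported in ng/L are converted to mU/L with
#' the manufacturer's factor 0.023. All internal computations in this
#' package use mU/L; ng/L is accepted only at the input boundary.
#'
#' @param x Insulin concentration(s) in ng/L; non-negative.
#' @return Insulin in mU/L.
#' @examples
#' insulin_ngL_to_mUL(100)  # 2.3
#' @export
insulin_ngL_to_mUL <- function(x) {
  stopifnot(is.numeric(x))
  if (any(x < 0, na.rm = TRUE))
    stop("insulin concentration cannot be negative", call. = FALSE)
  0.023 * x
}

#' Classify body condition score as lean or overweight
#'
#' Cats scored on the 9-point scale are lean when BCS <= 5 and overweight
#' when BCS >= 6; on the 5-point scale lean when BCS <= 3 and overweight
#' when BCS >= 4. The thresholds are integer so the mapping is unambiguous.
#'
#' @param bcs_value Integer body condition score(s).
#' @param bcs_scale Scale of the score, 5 or 9 (recycled).
#' @return Factor with levels `lean`, `overweight`.
#' @examples
#' classify_bcs(5, 9)  # lean
#' classify_bcs(4, 5)  # overweight
#' @export
classify_bcs <- function(bcs_value, bcs_scale) {
  stopifnot(is.numeric(bcs_value), is.numeric(bcs_scale))
  n <- max(length(bcs_value), length(bcs_scale))
  bcs_value <- rep_len(bcs_value, n)
  bcs_scale <- rep_len(bcs_scale, n)
  if (!all(bcs_scale %in% c(5, 9)))
    stop("bcs_scale must be 5 or 9", call. = FALSE)
  bad <- !is.na(bcs_value) &
    (bcs_value != round(bcs_value) | bcs_value < 1 | bcs_value > bcs_scale)
  if (any(bad))
    stop("bcs_value must be an integer within 1..bcs_scale", call. = FALSE)
  lean <- ifelse(bcs_scale == 9, bcs_value <= 5, bcs_value <= 3)
  factor(ifelse(lean, "lean", "overweight"),
         levels = c("lean", "overweight"))
}

#' Classify body fat percentage
#'
#' Three-way adiposity classes from CT-derived body fat percentage:
#' lean below 35, overweight in \[35, 45), obese at or above 45. The
#' intervals are closed on the left, so exactly 35 is overweight and
#' exactly 45 is obese.
#'
#' @param bf_percent Body fat percentage(s), strictly inside (0, 100).
#' @return Factor with levels `lean`, `overweight`, `obese`.
#' @examples
#' classify_bf(c(34.9, 35, 61.9))
#' @export
classify_bf <- function(bf_percent) {
  stopifnot(is.numeric(bf_percent))
  if (any(bf_percent <= 0 | bf_percent >= 100, na.rm = TRUE))
    stop("bf_percent must lie strictly inside (0, 100)", call. = FALSE)
  cut(bf_percent, breaks = c(0, 35, 45, 100),
      labels = c("lean", "overweight", "obese"), right = FALSE)
}
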