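#' Hounsfield-unit histogram of a masked CT volume
#'
#' Bins pre-masked whole-body CT voxel values inside the soft-tissue /
#' fat window (inclusive, default -250 to +250 HU). Voxels outside the
#' window — air, bone, and anything set to background by the upstream
#' segmentation — are discarded from the analysis set. Bins are centred
#' on the HU values (for the default 1-HU width, one bin per integer HU),
#' so integer voxel data yield integer peak positions.
#'
#' @param voxels Numeric vector of HU values (already masked; removal of
#'   urine, table and external objects is upstream of this package).
#' @param bin_width Bin width in HU.
#' @param window Inclusive HU window analysed.
#' @return Object of class `hu_histogram`: `bin_mid`, `counts`,
#'   `bin_width`, `window`, `n_total` (input voxels) and `n_window`
#'   (voxels inside the window).
#' @examples
#' h <- hu_histogram(c(-100, -100, -100, 60, 60))
#' sum(h$counts)
#' @export
hu_histogram <- function(voxels, bin_width = 1, window = c(-250, 250)) {
  stopifnot(is.numeric(voxels), bin_width > 0, length(window) == 2,
            window[1] < window[2])
  voxels <- voxels[!is.na(voxels)]
  if (length(voxels) == 0) stop("no voxels supplied", call. = FALSE)
  inside <- voxels >= window[1] & voxels <= window[2]
  v <- voxels[inside]
  if (length(v) == 0)
    stop("no voxels inside the HU window", call. = FALSE)
  mids <- seq(window[1], window[2], by = bin_width)
  edges <- c(mids - bin_width / 2, mids[length(mids)] + bin_width / 2)
  counts <- tabulate(findInterval(v, edges, rightmost.closed = TRUE),
                     nbins = length(mids))
  structure(list(bin_mid = mids, counts = counts, bin_width = bin_width,
                 window = window, n_total = length(voxels),
                 n_window = length(v)),
            class = "hu_histogram")
}

#' Read a precomputed HU frequency histogram
#'
#' Reads a two-column CSV (`bin_low`, `count`) as produced by image
#' software frequency exports, converting bin lower edges to centres.
#'
#' @param path CSV path.
#' @param bin_width Bin width the file was exported at.
#' @param window Inclusive HU window; bins outside are dropped.
#' @return An `hu_histogram` object.
#' @export
read_hu_histogram <- function(path, bin_width = 1, window = c(-250, 250)) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("bin_low", "count") %in% names(x)))
  mids_all <- seq(window[1], window[2], by = bin_width)
  counts <- numeric(length(mids_all))
  mid_in <- x$bin_low + bin_width / 2
  keep <- mid_in >= window[1] - bin_width / 2 &
    mid_in <= window[2] + bin_width / 2
  idx <- round((mid_in[keep] - window[1]) / bin_width) + 1
  ok <- idx >= 1 & idx <= length(mids_all)
  counts[idx[ok]] <- counts[idx[ok]] + x$count[keep][ok]
  if (sum(counts) == 0) stop("histogram empty inside window", call. = FALSE)
  structure(list(bin_mid = mids_all, counts = counts, bin_width = bin_width,
                 window = window, n_total = sum(x$count),
                 n_window = sum(counts)),
            class = "hu_histogram")
}

#' Locate the fat and lean attenuation peaks and their midpoint
#'
#' A masked feline CT histogram in the -250..+250 HU window is bimodal:
#' a fat-attenuation mode near -100 HU and a lean-soft-tissue mode near
#' +40..+60 HU. After moving-average smoothing (default width 5 bins)
#' the fat peak is the argmax over `fat_region` and the lean peak the
#' argmax over `lean_region`; the classification midpoint is their
#' arithmetic mean. Ties within a region are broken toward the bin
#' nearer the window centre.
#'
#' @param hist An [hu_histogram()].
#' @param smooth_width Moving-average width in bins (odd).
#' @param fat_region,lean_region HU intervals searched for each peak.
#' @return List with `fat_peak_hu`, `lean_peak_hu`, `midpoint_hu`.
#' @export
find_peaks_midpoint <- function(hist, smooth_width = 5,
                                fat_region = c(-250, -10),
                                lean_region = c(10, 250)) {
  stopifnot(inherits(hist, "hu_histogram"), smooth_width >= 1)
  sm <- smooth_counts(hist$counts, smooth_width)
  peak_in <- function(region) {
    in_reg <- hist$bin_mid >= region[1] & hist$bin_mid <= region[2]
    if (!any(in_reg) || all(hist$counts[in_reg] == 0))
      stop("unimodal histogram: no counts in search region [",
           region[1], ", ", region[2], "] HU", call. = FALSE)
    s <- sm[in_reg]; mids <- hist$bin_mid[in_reg]
    raw <- hist$counts[in_reg]
    tied <- s == max(s)
    # smoothing can flatten a sharp mode into a plateau: prefer the raw
    # maximum among tied bins, then the bin nearer the window centre
    cand <- mids[tied & raw == max(raw[tied])]
    cand[which.min(abs(cand))]
  }
  fat <- peak_in(fat_region)
  lean <- peak_in(lean_region)
  list(fat_peak_hu = fat, lean_peak_hu = lean,
       midpoint_hu = (fat + lean) / 2)
}

# centred moving average with shrinking windows at the edges
smooth_counts <- function(counts, width) {
  h <- floor(width / 2)
  n <- length(counts)
  vapply(seq_len(n), function(i)
    mean(counts[max(1, i - h):min(n, i + h)]), numeric(1))
}

#' Body fat percentage from an HU histogram and midpoint
#'
#' Voxels at or below the fat/lean midpoint (and inside the window) are
#' fat attenuation; voxels strictly above it are lean soft tissue. The
#' body fat percentage is `100 * n_fat / (n_fat + n_lean)`.
#'
#' @param hist An [hu_histogram()].
#' @param midpoint_hu Classification midpoint, inside the window.
#' @param peaks Optional peak list from [find_peaks_midpoint()], carried
#'   into the result.
#' @return Object of class `body_fat_result`: peak positions, midpoint,
#'   voxel counts, `bf_percent`, and the adiposity `category` from
#'   [classify_bf()].
#' @export
bf_percent <- function(hist, midpoint_hu, peaks = NULL) {
  stopifnot(inherits(hist, "hu_histogram"), is.numeric(midpoint_hu))
  if (midpoint_hu < hist$window[1] || midpoint_hu > hist$window[2])
    stop("midpoint outside the HU window", call. = FALSE)
  total <- sum(hist$counts)
  if (total == 0) stop("empty histogram", call. = FALSE)
  fat <- sum(hist$counts[hist$bin_mid <= midpoint_hu])
  lean <- total - fat
  bf <- 100 * fat / total
  structure(
    list(fat_peak_hu = peaks$fat_peak_hu %||% NA_real_,
         lean_peak_hu = peaks$lean_peak_hu %||% NA_real_,
         midpoint_hu = midpoint_hu,
         n_fat_voxels = fat, n_lean_voxels = lean,
         bf_percent = bf,
         category = if (bf > 0 && bf < 100) classify_bf(bf)
                    else factor(NA, levels = c("lean", "overweight", "obese"))),
    class = "body_fat_result")
}

#' Body fat percentage straight from masked voxels
#'
#' Convenience pipeline: histogram, peak and midpoint detection, then
#' fat/lean voxel classification.
#'
#' @param voxels Masked HU voxel values.
#' @param ... Passed to [hu_histogram()] and [find_peaks_midpoint()]
#'   (`bin_width`, `window`, `smooth_width`, `fat_region`, `lean_region`).
#' @return A `body_fat_result`.
#' @examples
#' v <- generate_phantom(n_voxels = 1e4, fat_fraction = 0.38, seed = 1)
#' body_fat(v)$bf_percent
#' @export
body_fat <- function(voxels, ...) {
  args <- list(...)
  hist_args <- args[names(args) %in% c("bin_width", "window")]
  peak_args <- args[names(args) %in%
                      c("smooth_width", "fat_region", "lean_region")]
  h <- do.call(hu_histogram, c(list(voxels), hist_args))
  p <- do.call(find_peaks_midpoint, c(list(h), peak_args))
  bf_percent(h, p$midpoint_hu, peaks = p)
}

#' @export
print.body_fat_result <- function(x, ...) {
  cat(sprintf("Body fat: %.1f%% (%s)\n", x$bf_percent,
              as.character(x$category)))
  cat(sprintf("  fat peak %s HU, lean peak %s HU, midpoint %s HU\n",
              format(x$fat_peak_hu), format(x$lean_peak_hu),
              format(x$midpoint_hu)))
  cat(sprintf("  voxels: %d fat, %d lean\n", x$n_fat_voxels,
              x$n_lean_voxels))
  invisible(x)
}

#' Predictive values of BCS classification against BF%
#'
#' With CT-derived body fat as the reference method (lean below 35%,
#' overweight/obese at or above), computes the negative predictive value
#' of a lean body condition score (fraction of BCS-lean cats that are
#' truly lean) and the positive predictive value of an overweight score
#' (fraction of BCS-overweight cats that are truly overweight or obese).
#'
#' @param cohort A `cat_cohort` (or data frame) with `bcs_value`,
#'   `bcs_scale` and `bf_percent`; rows without body fat are dropped.
#' @return List with `npv_pct`, `ppv_pct` (percent, full precision;
#'   report to 1 decimal), the 2x2 `counts` table, and `n`. An empty BCS
#'   class yields `NA` for the affected value, with a warning.
#' @examples
#' cohort <- generate_cohort(n = 68, seed = 3)
#' predictive_values(cohort)
#' @export
predictive_values <- function(cohort) {
  df <- as.data.frame(cohort)
  stopifnot(all(c("bcs_value", "bcs_scale", "bf_percent") %in% names(df)))
  df <- df[!is.na(df$bf_percent), , drop = FALSE]
  if (nrow(df) == 0) stop("no cats with measured body fat", call. = FALSE)
  bcs <- classify_bcs(df$bcs_value, df$bcs_scale)
  bf_lean <- df$bf_percent < 35
  counts <- table(bcs = bcs, bf = factor(ifelse(bf_lean, "lean",
                                                "overweight_obese"),
                                         levels = c("lean",
                                                    "overweight_obese")))
  n_bcs_lean <- sum(counts["lean", ])
  n_bcs_over <- sum(counts["overweight", ])
  npv <- if (n_bcs_lean > 0) 100 * counts["lean", "lean"] / n_bcs_lean
         else NA_real_
  ppv <- if (n_bcs_over > 0)
    100 * counts["overweight", "overweight_obese"] / n_bcs_over
  else NA_real_
  if (is.na(npv) || is.na(ppv))
    warning("empty BCS class; predictive value undefined", call. = FALSE)
  list(npv_pct = npv, ppv_pct = ppv, counts = counts, n = nrow(df))
}
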