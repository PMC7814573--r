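#' Analysis configuration
#'
#' Bundles every tunable of the pipeline with an explicit default so that
#' each run can serialise the exact settings it used. Values the source
#' data never pin down (notably the fructosamine cut-off used to call
#' suspected diabetes in hyperglycemic cats) are site-configurable and
#' must be reviewed against the local laboratory's reference interval.
#'
#' @param z_value Two-sided standard-normal quantile used for reference
#'   change values and Wald intervals; 1.96 corresponds to 95% probability.
#' @param rcv_probability Two-sided probability the RCV refers to.
#' @param bootstrap_B Number of bootstrap resamples for reference-interval
#'   confidence limits.
#' @param rng_seed Integer seed recorded with the run.
#' @param glucose_dm_threshold_mmolL Fasting glucose above which
#'   fructosamine is consulted to separate stress hyperglycemia from
#'   diabetes mellitus.
#' @param fructosamine_threshold_umolL Fructosamine above which a
#'   hyperglycemic cat is treated as diabetes-suspected. Site-configurable;
#'   the default of 400 umol/L is a common upper reference limit for cats,
#'   not a study-derived constant.
#' @param histogram_bin_width_HU Bin width for CT Hounsfield-unit
#'   histograms.
#' @param hu_window Two-element integer vector, the inclusive HU window
#'   analysed for body composition.
#'
#' @return An object of class `analysis_config` (a named list).
#' @examples
#' cfg <- analysis_config(rng_seed = 7)
#' cfg$z_value
#' @export
analysis_config <- function(z_value = 1.96,
                            rcv_probability = 0.95,
                            bootstrap_B = 5000L,
                            rng_seed = 1L,
                            glucose_dm_threshold_mmolL = 10,
                            fructosamine_threshold_umolL = 400,
                            histogram_bin_width_HU = 1,
                            hu_window = c(-250L, 250L)) {
  stopifnot(z_value > 0, rcv_probability > 0, rcv_probability < 1,
            bootstrap_B >= 1, glucose_dm_threshold_mmolL > 0,
            fructosamine_threshold_umolL > 0, histogram_bin_width_HU > 0,
            length(hu_window) == 2, hu_window[1] < hu_window[2])
  structure(
    list(z_value = z_value,
         rcv_probability = rcv_probability,
         bootstrap_B = as.integer(bootstrap_B),
         rng_seed = as.integer(rng_seed),
         glucose_dm_threshold_mmolL = glucose_dm_threshold_mmolL,
         fructosamine_threshold_umolL = fructosamine_threshold_umolL,
         histogram_bin_width_HU = histogram_bin_width_HU,
         hu_window = as.integer(hu_window)),
    class = "analysis_config")
}

#' Write a run manifest
#'
#' Serialises the fully resolved configuration, and optionally an
#' exclusion report, as JSON so a run can be audited and reproduced.
#'
#' @param cfg An [analysis_config()] object.
#' @param path File to write; use `""` for stdout.
#' @param exclusion_report Optional exclusion report from
#'   [apply_exclusions()].
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(cfg, path, exclusion_report = NULL) {
  stopifnot(inherits(cfg, "analysis_config"))
  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(cfg))
  if (!is.null(exclusion_report)) {
    stopifnot(inherits(exclusion_report, "exclusion_report"))
    manifest$exclusions <- list(
      retained_count = exclusion_report$retained_count,
      followup = exclusion_report$followup,
      excluded = exclusion_report$excluded)
  }
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(manifest)
}
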