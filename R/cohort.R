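#' @importFrom tibble tibble as_tibble
NULL

# canonical column order of a cohort table
cohort_columns <- c(
  "cat_id", "age_years", "sex", "neutered", "breed", "bcs_value",
  "bcs_scale", "insulin_mUL", "glucose_mmolL", "fructosamine",
  "bf_percent", "stressed", "locomotor_signs", "insulin_interference",
  "fasted", "pregnant")

cohort_mandatory <- c("cat_id", "age_years", "sex", "bcs_value",
                      "bcs_scale", "glucose_mmolL")

#' Validate a cohort table of cat records
#'
#' Checks one-row-per-cat clinical data against the domain invariants:
#' strictly positive insulin and glucose, body condition score within its
#' declared scale (5 or 9 point), body fat percentage inside (0, 100),
#' non-negative age. Rows violating an invariant are dropped with a
#' warning that lists the row numbers and reasons; validation only fails
#' outright when a mandatory column is missing or no row survives.
#'
#' Optional columns (`neutered`, `breed`, `fructosamine`, `bf_percent`,
#' and the boolean flags) are filled with their neutral defaults when
#' absent. Insulin may be supplied as `insulin_mUL`, or as `insulin_ngL`
#' which is converted with [insulin_ngL_to_mUL()] on entry.
#'
#' @param x A data frame with at least the mandatory cohort columns.
#' @return A validated tibble of class `cat_cohort` with the canonical
#'   column set; attribute `row_errors` holds a tibble of rejected rows.
#' @export
validate_cohort <- function(x) {
  x <- as_tibble(x)
  if ("insulin_ngL" %in% names(x) && !"insulin_mUL" %in% names(x)) {
    x$insulin_mUL <- insulin_ngL_to_mUL(x$insulin_ngL)
    x$insulin_ngL <- NULL
  }
  missing_cols <- setdiff(c(cohort_mandatory, "insulin_mUL"), names(x))
  if (length(missing_cols) > 0)
    stop("cohort table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  defaults <- list(neutered = NA, breed = NA_character_,
                   fructosamine = NA_real_, bf_percent = NA_real_,
                   stressed = FALSE, locomotor_signs = FALSE,
                   insulin_interference = FALSE, fasted = TRUE,
                   pregnant = FALSE)
  for (nm in names(defaults))
    if (!nm %in% names(x)) x[[nm]] <- defaults[[nm]]

  err <- character(nrow(x))
  note <- function(bad, msg) {
    bad <- !is.na(bad) & bad
    err[bad] <<- ifelse(err[bad] == "", msg, paste(err[bad], msg, sep = "; "))
  }
  note(!is.finite(x$insulin_mUL) | x$insulin_mUL <= 0,
       "insulin must be > 0")
  note(!is.finite(x$glucose_mmolL) | x$glucose_mmolL <= 0,
       "glucose must be > 0")
  note(!x$bcs_scale %in% c(5, 9), "bcs_scale must be 5 or 9")
  note(x$bcs_scale %in% c(5, 9) &
         (x$bcs_value != round(x$bcs_value) | x$bcs_value < 1 |
            x$bcs_value > x$bcs_scale),
       "bcs_value outside 1..bcs_scale")
  note(x$age_years < 0, "age_years must be non-negative")
  note(!is.na(x$bf_percent) & (x$bf_percent <= 0 | x$bf_percent >= 100),
       "bf_percent outside (0, 100)")
  note(!is.na(x$fructosamine) & x$fructosamine < 0,
       "fructosamine must be non-negative")

  bad <- err != ""
  row_errors <- tibble(row = which(bad), message = err[bad])
  if (all(bad) && nrow(x) > 0)
    stop("no cohort row passed validation; first error: ",
         row_errors$message[1], call. = FALSE)
  if (any(bad))
    warning(sprintf("dropped %d invalid cohort row(s): %s", sum(bad),
                    paste0("row ", row_errors$row, " (",
                           row_errors$message, ")", collapse = ", ")),
            call. = FALSE)
  out <- x[!bad, cohort_columns]
  structure(out, row_errors = row_errors,
            class = c("cat_cohort", class(out)))
}

#' Read a cohort table from CSV
#'
#' Reads an RFC-4180 CSV with a header row whose names map to the cohort
#' schema, then validates it with [validate_cohort()]. Insulin unit is
#' declared either by the column name (`insulin_mUL` or `insulin_ngL`) or
#' through `insulin_unit` when the file uses a bare `insulin` column.
#'
#' @param path Path to the CSV file.
#' @param insulin_unit Unit of a bare `insulin` column, `"mU/L"` or
#'   `"ng/L"`. Ignored when the column name itself declares the unit.
#' @return A validated `cat_cohort` tibble.
#' @export
read_cohort <- function(path, insulin_unit = c("mU/L", "ng/L")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  insulin_unit <- match.arg(insulin_unit)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("insulin" %in% names(x) &&
      !any(c("insulin_mUL", "insulin_ngL") %in% names(x))) {
    names(x)[names(x) == "insulin"] <-
      if (insulin_unit == "ng/L") "insulin_ngL" else "insulin_mUL"
  }
  validate_cohort(x)
}

#' Write a cohort table to CSV
#'
#' Round-trips losslessly with [read_cohort()] for all schema fields.
#'
#' @param cohort A `cat_cohort` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cat_cohort"))
  readr::write_csv(as_tibble(as.data.frame(cohort)), path, progress = FALSE)
  invisible(path)
}

# fixed precedence of exclusion reasons; a cat is reported once, under the
# first reason that applies
exclusion_reasons <- c("stressed", "underage", "pregnant", "nonfasted",
                       "diabetes_suspected", "insulin_interference")

#' Screen a cohort and apply the exclusion rules
#'
#' Removes cats that are stressed at sampling, younger than one year,
#' pregnant, non-fasted, suspected diabetic (glucose above the
#' configured threshold *and* fructosamine above the configured cut-off),
#' or flagged for insulin assay interference. Hyperglycemic cats whose
#' fructosamine is normal or unmeasured are *retained* — consistent with
#' stress hyperglycemia — and listed for follow-up in the report. The
#' filter is idempotent and each excluded cat is reported once, under the
#' first applicable reason in the fixed order stressed, underage,
#' pregnant, nonfasted, diabetes_suspected, insulin_interference.
#'
#' @param cohort A validated `cat_cohort` tibble.
#' @param cfg An [analysis_config()]; supplies the glucose and
#'   fructosamine thresholds and is embedded in the report so every run
#'   logs its resolved settings.
#' @return A list with `retained` (the filtered `cat_cohort`) and
#'   `report` (class `exclusion_report`: `excluded` tibble of
#'   cat_id/reason, `retained_count`, `followup` cat ids, `config`).
#' @examples
#' cohort <- generate_cohort(n = 30, seed = 1)
#' res <- apply_exclusions(cohort, analysis_config())
#' res$report$retained_count
#' @export
apply_exclusions <- function(cohort, cfg = analysis_config()) {
  stopifnot(inherits(cohort, "cat_cohort"), inherits(cfg, "analysis_config"))
  hyperglycemic <- cohort$glucose_mmolL > cfg$glucose_dm_threshold_mmolL
  dm_suspected <- hyperglycemic & !is.na(cohort$fructosamine) &
    cohort$fructosamine > cfg$fructosamine_threshold_umolL
  reason_hits <- cbind(
    stressed = cohort$stressed %in% TRUE,
    underage = cohort$age_years < 1,
    pregnant = cohort$pregnant %in% TRUE,
    nonfasted = !(cohort$fasted %in% c(TRUE, NA)),
    diabetes_suspected = dm_suspected,
    insulin_interference = cohort$insulin_interference %in% TRUE)
  any_hit <- rowSums(reason_hits) > 0
  first_reason <- apply(reason_hits, 1L, function(r)
    if (any(r)) exclusion_reasons[which(r)[1]] else NA_character_)

  retained <- cohort[!any_hit, , drop = FALSE]
  followup <- retained$cat_id[retained$glucose_mmolL >
                                cfg$glucose_dm_threshold_mmolL]
  report <- structure(
    list(excluded = tibble(cat_id = cohort$cat_id[any_hit],
                           reason = first_reason[any_hit]),
         retained_count = nrow(retained),
         followup = followup,
         config = unclass(cfg)),
    class = "exclusion_report")
  list(retained = retained, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Cohort exclusion report\n")
  cat(sprintf("  retained: %d   excluded: %d\n",
              x$retained_count, nrow(x$excluded)))
  if (nrow(x$excluded) > 0)
    print(table(factor(x$excluded$reason, levels = exclusion_reasons)))
  if (length(x$followup) > 0)
    cat("  hyperglycemic, fructosamine normal/absent (follow-up):",
        paste(x$followup, collapse = ", "), "\n")
  invisible(x)
}
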