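# Plain-text interchange formats. Profiles travel as long CSV
# (subject_id, route, time_hr, conc_ng_ml, dose, body_weight_kg,
# removal_time_hr); a `time_min` column is accepted and converted to hours
# on ingest. Patch residuals, cohort tables and daily records are flat CSV;
# analysis reports are JSON.

#' Read a concentration-time profile table
#'
#' Reads the long CSV profile format, converting a `time_min` column to
#' `time_hr` when present, and validates each subject's profile (strictly
#' increasing times, at least 3 samples, finite non-negative
#' concentrations).
#'
#' @param path CSV file path.
#' @return Long profile tibble.
#' @export
read_profiles <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if ("time_min" %in% names(x) && !"time_hr" %in% names(x)) {
    x <- mutate(x, time_hr = .data$time_min / 60) %>% select(-"time_min")
  }
  x %>%
    group_by(.data$subject_id, .data$route) %>%
    dplyr::group_walk(~ validate_profile(.x)) %>%
    ungroup()
}

#' Write a profile table
#' @param profiles Long profile tibble.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  readr::write_csv(profiles, path)
  invisible(path)
}

#' Read a patch-residual assay table
#'
#' Columns: `subject_id`, `x_unused_ug`, `x_used_ug`; joined to profiles by
#' `subject_id` downstream.
#'
#' @param path CSV file path.
#' @return Tibble.
#' @export
read_patch_residuals <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("subject_id", "x_unused_ug", "x_used_ug")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(paste("Residual table missing:", toString(miss)))
  if (any(x$x_used_ug > x$x_unused_ug)) {
    abort("Residual exceeds unused content: inconsistent assay values.")
  }
  x
}

#' Read a cohort table
#'
#' One row per patient; comorbidity indicators are 0/1 columns named by
#' their ICD-10 code.
#'
#' @param path CSV file path.
#' @return Tibble.
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read long-format daily medication records
#'
#' Columns: `patient_id`, `day`, `dose_mg`, `rescue_count`.
#'
#' @param path CSV file path.
#' @return Tibble.
#' @export
read_daily_records <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("patient_id", "day", "dose_mg", "rescue_count")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(paste("Record table missing:", toString(miss)))
  x
}

#' Write an analysis report as JSON
#'
#' Serialises any of the package's tibble results (or a named list of them)
#' to pretty-printed JSON, together with a provenance block (package
#' version, timestamp, and any extra fields such as the seed).
#'
#' @param result Tibble or named list of tibbles.
#' @param path Output JSON path.
#' @param ... Extra provenance fields (e.g. `seed = 1`).
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, ...) {
  payload <- list(
    provenance = c(list(
      package = "tdfent",
      version = as.character(utils::packageVersion("tdfent")),
      created = format(Sys.time(), tz = "UTC", usetz = TRUE)
    ), list(...)),
    result = result
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
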