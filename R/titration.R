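# Titration-period extraction from longitudinal medication records.
# The period is the first day T (counted from initiation, day 1) ending a
# `stability_days`-day window in which the dose never changes and every
# day's rescue-opioid count is within `rescue_max`; by construction the
# minimum attainable period equals `stability_days`.

#' Extract the titration period from daily records
#'
#' For each patient, returns the smallest day `T >= stability_days` such
#' that over the `stability_days` consecutive days ending at `T` the dose is
#' constant and (under the default `"window"` convention) every day's rescue
#' count is `<= rescue_max`. The `"final_day"` convention applies the rescue
#' ceiling only on day `T` itself. Patients with no qualifying window in
#' their record are censored: their period is `NA` and they are excluded
#' from the two-group comparison downstream.
#'
#' @param records Long tibble with `patient_id`, `day` (1 = initiation,
#'   contiguous), `dose_mg`, `rescue_count`.
#' @param stability_days Length of the no-dose-change window (days).
#' @param rescue_max Maximum daily rescue count compatible with stability.
#' @param rescue_rule `"window"` (default) or `"final_day"` (see above).
#' @return Tibble, one row per patient: `titration_period` (days, `NA` if
#'   censored), `censored`.
#' @examples
#' rec <- tibble::tibble(patient_id = "a", day = 1:8,
#'                       dose_mg = 1, rescue_count = c(1, 1, 4, 0, 1, 0, 2, 1))
#' titration_period(rec)  # first window clear of day 3 ends on day 8
#' @export
titration_period <- function(records, stability_days = 5, rescue_max = 3,
                             rescue_rule = c("window", "final_day")) {
  rescue_rule <- arg_match(rescue_rule)
  records <- as_tibble(records)
  need <- c("patient_id", "day", "dose_mg", "rescue_count")
  miss <- setdiff(need, names(records))
  if (length(miss)) abort(paste("`records` missing columns:", toString(miss)))

  d <- arrange(records, .data$patient_id, .data$day)
  if (any(d$dose_mg <= 0)) abort("Doses must be positive.")
  if (any(d$rescue_count < 0)) abort("Rescue counts cannot be negative.")
  idx <- seq_len(nrow(d))
  new_patient <- !duplicated(d$patient_id)
  # validate contiguity: day restarts at 1 on each patient and increments
  expected_day <- idx - cummax(ifelse(new_patient, idx, 0L)) + 1L
  if (!all(d$day == expected_day)) {
    abort("`day` must run contiguously from 1 within each patient.")
  }
  n_days <- tapply(d$day, d$patient_id, length)
  if (any(n_days < stability_days)) {
    abort("Record shorter than the stability window.")
  }

  # run length of unchanged dose ending at each row (resets at patient
  # boundaries and at any dose change)
  reset <- new_patient | c(TRUE, d$dose_mg[-1] != d$dose_mg[-nrow(d)])
  run <- idx - cummax(ifelse(reset, idx, 0L)) + 1L
  dose_ok <- run >= stability_days & d$day >= stability_days

  viol <- d$rescue_count > rescue_max
  if (rescue_rule == "window") {
    # most recent violation row at or before each row; a window ending here
    # is clean iff that violation (if any, and in this patient) precedes it
    last_viol <- cummax(ifelse(viol, idx, 0L))
    patient_start <- cummax(ifelse(new_patient, idx, 0L))
    viol_day <- ifelse(last_viol >= patient_start,
                       last_viol - patient_start + 1L, 0L)
    rescue_ok <- viol_day <= d$day - stability_days
  } else {
    rescue_ok <- !viol
  }

  qualifies <- dose_ok & rescue_ok
  first_hit <- qualifies &
    !duplicated(ifelse(qualifies, as.character(d$patient_id), NA_character_))

  found <- tibble(patient_id = d$patient_id[first_hit],
                  titration_period = as.integer(d$day[first_hit]),
                  censored = FALSE)
  all_ids <- unique(d$patient_id)
  censored_ids <- setdiff(all_ids, found$patient_id)
  bind_rows(found,
            tibble(patient_id = censored_ids,
                   titration_period = NA_integer_, censored = TRUE)) %>%
    arrange(match(.data$patient_id, all_ids))
}

#' Dichotomize titration periods into short and long groups
#'
#' Adds the binary study outcome: 1 for a titration period of `cutoff + 1`
#' days or more ("6 days or more" under the default cutoff of 5), 0 for a
#' period within `cutoff` days. Censored patients (no qualifying window) are
#' dropped; their count is attached as the `"n_censored"` attribute and
#' reported in a message.
#'
#' @param outcomes Tibble from [titration_period()].
#' @param cutoff Largest period (days) counted as a short titration.
#' @return `outcomes` without censored rows, plus `long_titration` (0/1) and
#'   `group` (`"within_5"` / `"six_or_more"` style labels).
#' @export
dichotomize <- function(outcomes, cutoff = 5) {
  n_censored <- sum(outcomes$censored)
  if (n_censored > 0) {
    inform(sprintf("Dropping %d censored record(s) with no qualifying window.",
                   n_censored))
  }
  out <- outcomes %>%
    filter(!.data$censored) %>%
    mutate(
      long_titration = as.integer(.data$titration_period >= cutoff + 1),
      group = ifelse(.data$long_titration == 1,
                     sprintf("%d_or_more", cutoff + 1),
                     sprintf("within_%d", cutoff))
    )
  attr(out, "n_censored") <- n_censored
  out
}
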