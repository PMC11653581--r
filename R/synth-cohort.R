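# Virtual patient-cohort generator for the titration arm. Covariates and
# comorbidity indicators are drawn from the cohort preset, the binary
# long-titration outcome from a logistic model on the comorbidity
# indicators, and each patient's daily dose / rescue record is constructed
# so that the titration rule recovers exactly the period implied by the
# drawn outcome (constructive round-trip).

#' Simulate a virtual patient cohort with daily records
#'
#' Draws `n` patients with independent covariates (gender Bernoulli;
#' age, height, BMI and serum albumin log-normal, matched to the preset
#' medians and interquartile ranges; weight derived from BMI and height;
#' albumin set missing for a preset fraction) and independent Bernoulli
#' comorbidity indicators. The long-titration outcome probability is
#' `plogis(b0 + sum(log_odds * flags))`; the intercept `b0` is calibrated on
#' the realised linear predictors so the cohort's expected outcome fraction
#' equals the preset target (126/387 by default). Patients with outcome 0
#' get titration period 5 (dose stable, rescues in range from day 1);
#' patients with outcome 1 get a period drawn from 6 upward with a geometric
#' tail, capped at the preset maximum. Daily records are then built so the
#' window rule returns exactly that period: every day more than 5 days
#' before the qualifying day carries > `rescue_max` rescues, the final
#' window is dose-stable with rescues in range, and half of the long
#' titrations also carry a dose step at the start of the final window.
#'
#' @param preset A [cohort_preset()] list.
#' @param seed Integer seed; required.
#' @return List of class `"cohort_study"`: `$cohort` (one row per patient:
#'   `patient_id`, `female`, `age`, `height`, `weight`, `bmi`, `albumin`,
#'   `initial_dose`, one 0/1 column per comorbidity code), `$records`
#'   (`patient_id`, `day`, `dose_mg`, `rescue_count`), `$truth`
#'   (`patient_id`, `p_outcome`, `outcome`, `period`), `$intercept` (the
#'   calibrated `b0`), `$preset`.
#' @examples
#' cohort <- simulate_cohort(cohort_preset(n = 50), seed = 7)
#' mean(cohort$truth$outcome)
#' @export
simulate_cohort <- function(preset, seed) {
  if (missing(seed)) abort("`seed` is required for reproducibility.")
  set.seed(seed)
  n <- preset$n

  prev <- preset$comorbidity_prevalence
  low <- prev * n < 1
  if (any(low)) {
    warn(paste("Near-degenerate comorbidity factor(s):",
               toString(names(prev)[low])))
  }
  flags <- vapply(prev, function(p) rbinom(n, 1, p), integer(n))
  colnames(flags) <- names(prev)

  height <- rlnorm(n, preset$height$meanlog, preset$height$sdlog)
  bmi <- rlnorm(n, preset$bmi$meanlog, preset$bmi$sdlog)
  albumin <- rlnorm(n, preset$albumin$meanlog, preset$albumin$sdlog)
  albumin[runif(n) < preset$albumin_missing_fraction] <- NA_real_

  cohort <- tibble(
    patient_id = sprintf("pt_%04d", seq_len(n)),
    female = as.integer(runif(n) >= preset$male_fraction),
    age = rlnorm(n, preset$age$meanlog, preset$age$sdlog),
    height = height,
    bmi = bmi,
    weight = bmi * (height / 100)^2,
    albumin = albumin,
    initial_dose = sample(preset$initial_dose_levels, n, replace = TRUE,
                          prob = preset$initial_dose_probs)
  ) %>%
    dplyr::bind_cols(as_tibble(flags))

  lp <- drop(flags %*% preset$outcome_log_odds[colnames(flags)])
  b0 <- calibrate_intercept(lp, preset$target_outcome_fraction)
  p_outcome <- stats::plogis(b0 + lp)
  outcome <- rbinom(n, 1, p_outcome)

  period <- ifelse(outcome == 1,
                   pmin(6 + rgeom(n, preset$long_period_geom_prob),
                        preset$max_period),
                   5L)

  records <- build_titration_records(cohort$patient_id, period,
                                     cohort$initial_dose)

  structure(list(
    cohort = cohort,
    records = records,
    truth = tibble(patient_id = cohort$patient_id, p_outcome = p_outcome,
                   outcome = outcome, period = as.integer(period)),
    intercept = b0,
    preset = preset
  ), class = "cohort_study")
}

# Solve mean(plogis(b0 + lp)) = target for b0 on the realised linear
# predictors: exact calibration of the cohort's expected outcome fraction.
calibrate_intercept <- function(lp, target) {
  uniroot(function(b0) mean(stats::plogis(b0 + lp)) - target,
          c(-20, 20), tol = 1e-12)$root
}

# Build daily dose / rescue sequences whose extracted titration period is
# exactly `period` for every patient (stability window 5 days, rescue
# ceiling 3/day): every day more than 5 days before the qualifying day
# violates the rescue ceiling, the final window is dose-stable with rescues
# in range, and half of the long titrations also carry a dose step when the
# violating prefix ends.
build_titration_records <- function(patient_id, period, initial_dose,
                                    extra_days = 2) {
  len <- period + extra_days
  pat <- rep.int(seq_along(patient_id), len)
  day <- sequence(len)
  viol <- day <= period[pat] - 5
  rescue <- ifelse(viol,
                   sample(4:8, length(day), replace = TRUE),
                   sample(0:3, length(day), replace = TRUE))
  step <- period > 5 & runif(length(period)) < 0.5
  dose <- ifelse(step[pat] & day >= period[pat] - 4,
                 2 * initial_dose[pat], initial_dose[pat])
  tibble(patient_id = patient_id[pat], day = as.integer(day),
         dose_mg = dose, rescue_count = as.integer(rescue))
}

#' @export
print.cohort_study <- function(x, ...) {
  cat(sprintf(
    "Virtual cohort: %d patients, %d with long titration (fraction %.3f)\n",
    nrow(x$cohort), sum(x$truth$outcome), mean(x$truth$outcome)))
  invisible(x)
}
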