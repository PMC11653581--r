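# Virtual-rat study generator: per-animal IV bolus and transdermal profiles
# at the study's sampling schedules, plus matching patch-residual assays.
# Between-animal variability is log-normal on k_a, clearance and F
# (mean-preserving), measurement error is proportional log-normal (mean 1).

#' Simulate a virtual-rat PK study
#'
#' For each animal: draw body weight (normal) and mean-preserving log-normal
#' between-animal deviates on `k_a`, clearance and `F`; the animal's `k_e`
#' is its clearance over the (fixed) `Vd_ss`, so disposition stays
#' internally consistent. Simulate the IV bolus curve at the preset's
#' minute schedule and the transdermal curve at its hour schedule via the
#' closed-form one-compartment models, then multiply every sample by a
#' proportional log-normal error (mean 1, CV `error_cv`). Emit a matching
#' patch-residual assay with
#' `X_used = X_unused * (1 - F_a * (1 + assay noise))`, truncated to the
#' physical range.
#'
#' @param preset A [rat_preset()] list.
#' @param n_subjects Number of animals (>= 1).
#' @param error_cv Proportional measurement-error CV (default 0.10).
#' @param iiv_cv Between-animal CV. `NULL` (default) uses the preset's
#'   per-parameter CVs (S.D./mean of the strain summary); a single number
#'   applies that CV to `k_a`, clearance and `F` alike; 0 disables
#'   between-animal variability.
#' @param seed Integer seed; required, the generator is fully reproducible.
#' @param dialect Depot semantics for the transdermal curve (see
#'   [bateman_concentration()]).
#' @return List of class `"rat_study"`: `$profiles` (long tibble:
#'   `subject_id`, `strain`, `route`, `time_hr`, `conc_ng_ml`, `dose`,
#'   `body_weight_kg`, `removal_time_hr`), `$residuals` (`subject_id`,
#'   `x_unused_ug`, `x_used_ug`), `$subjects` (the generating per-animal
#'   parameters), `$preset`.
#' @examples
#' study <- simulate_rat(rat_preset("gk"), n_subjects = 5, seed = 1)
#' dplyr::count(study$profiles, route)
#' @export
simulate_rat <- function(preset, n_subjects, error_cv = 0.10, iiv_cv = NULL,
                         seed, dialect = c("full_depot", "truncated_input")) {
  dialect <- arg_match(dialect)
  if (missing(seed)) abort("`seed` is required for reproducibility.")
  if (n_subjects < 1) abort("`n_subjects` must be at least 1.")
  if (error_cv < 0) abort("`error_cv` cannot be negative.")
  if (!is.null(iiv_cv) && any(iiv_cv < 0)) abort("`iiv_cv` cannot be negative.")
  set.seed(seed)

  cvs <- if (is.null(iiv_cv)) {
    c(k_a = preset$cv_k_a, cl = preset$cv_cl, F = preset$cv_F)
  } else {
    c(k_a = iiv_cv, cl = iiv_cv, F = iiv_cv)
  }
  cl_nominal <- preset$k_e * preset$Vd_ss

  subjects <- tibble(
    subject_id = sprintf("%s_%02d", preset$label, seq_len(n_subjects)),
    strain = preset$label,
    body_weight_kg = rnorm(n_subjects, preset$body_weight_mean,
                           preset$body_weight_sd),
    k_a = lnorm_mean_preserving(n_subjects, preset$k_a, cvs[["k_a"]]),
    CL = lnorm_mean_preserving(n_subjects, cl_nominal, cvs[["cl"]]),
    F_bio = pmin(lnorm_mean_preserving(n_subjects, preset$F, cvs[["F"]]), 0.995),
    F_a = preset$F_a
  ) %>%
    mutate(k_e = .data$CL / preset$Vd_ss, Vd_ss = preset$Vd_ss)

  iv_times <- preset$iv_schedule_min / 60
  td_times <- preset$td_schedule_hr

  profiles <- purrr::pmap(subjects, function(subject_id, strain,
                                             body_weight_kg, k_a, CL, F_bio,
                                             F_a, k_e, Vd_ss) {
    iv_true <- iv_bolus_concentration(iv_times, preset$iv_dose, k_e, Vd_ss)
    td_true <- bateman_concentration(td_times, preset$td_dose, F_bio, k_a,
                                     k_e, Vd_ss * body_weight_kg,
                                     removal_time = preset$removal_time,
                                     dialect = dialect)
    bind_rows(
      tibble(subject_id, strain, route = "iv_bolus", time_hr = iv_times,
             conc_ng_ml = iv_true * prop_error(length(iv_true), error_cv),
             dose = preset$iv_dose, body_weight_kg,
             removal_time_hr = NA_real_),
      tibble(subject_id, strain, route = "transdermal", time_hr = td_times,
             conc_ng_ml = td_true * prop_error(length(td_true), error_cv),
             dose = preset$td_dose, body_weight_kg,
             removal_time_hr = preset$removal_time)
    )
  }) %>% bind_rows()

  assay_noise <- rnorm(n_subjects, 0, preset$cv_F_a)
  residuals <- tibble(
    subject_id = subjects$subject_id,
    x_unused_ug = preset$td_dose,
    x_used_ug = pmin(pmax(
      preset$td_dose * (1 - subjects$F_a * (1 + assay_noise)), 0),
      preset$td_dose)
  )

  structure(list(profiles = profiles, residuals = residuals,
                 subjects = subjects, preset = preset),
            class = "rat_study")
}

# Log-normal draws with arithmetic mean `mean` and coefficient of variation
# `cv` (cv = 0 returns the mean exactly).
lnorm_mean_preserving <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Multiplicative proportional error with mean 1.
prop_error <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' @export
print.rat_study <- function(x, ...) {
  cat(sprintf("Virtual-rat study: %d %s animals, %d profile rows\n",
              nrow(x$subjects), x$preset$label, nrow(x$profiles)))
  invisible(x)
}
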