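# Transdermal bioavailability and its decomposition into patch release and
# skin availability: F = F_a * F_skin. F comes from the dose-corrected AUC
# ratio of each subject's transdermal profile against the group-mean IV AUC;
# F_a from the residual drug assay of the removed formulation.

#' Transdermal bioavailability from the AUC ratio
#'
#' `F = (AUC_td / dose_td_per_kg) / (mean_AUC_iv / dose_iv)`, i.e. each
#' subject's dose-normalised transdermal exposure divided by the group-mean
#' dose-normalised IV exposure. The group mean (not the same subject's IV
#' AUC) is the reference by design; set `mean_auc_iv` to a single subject's
#' AUC for a per-subject variant. Values above 1 are physically impossible
#' for a bioavailability and are returned with a warning, never clamped.
#'
#' @param auc_td Subject's transdermal `AUC_0_inf` (ng*hr/mL); vectorised.
#' @param dose_td Applied transdermal amount (ug, total).
#' @param body_weight Subject body weight (kg).
#' @param mean_auc_iv Group-mean IV `AUC_0_inf` (ng*hr/mL).
#' @param dose_iv IV dose (ug/kg).
#' @return Bioavailable fraction(s) in `[0, 1]` for clean data.
#' @examples
#' transdermal_F(auc_td = 88.6, dose_td = 160, body_weight = 0.305,
#'               mean_auc_iv = 3.12, dose_iv = 10)
#' @export
transdermal_F <- function(auc_td, dose_td, body_weight, mean_auc_iv, dose_iv) {
  # NA transdermal AUCs (flagged moment analyses) propagate as NA
  if (any(auc_td <= 0, na.rm = TRUE)) abort("`auc_td` must be positive.")
  check_positive(dose_td = dose_td, body_weight = body_weight,
                 mean_auc_iv = mean_auc_iv, dose_iv = dose_iv)
  F_bio <- (auc_td / (dose_td / body_weight)) / (mean_auc_iv / dose_iv)
  if (any(F_bio > 1, na.rm = TRUE)) {
    warn("Bioavailability above 1 computed; check AUCs and doses.")
  }
  F_bio
}

#' Release fraction from patch residuals
#'
#' Fraction of the formulation's content released during wear:
#' `F_a = (X_unused - X_used) / X_unused`, where `X_unused` is the drug
#' content of an unused formulation and `X_used` the residual in the removed
#' one.
#'
#' @param x_unused Content of the unused formulation (ug); vectorised.
#' @param x_used Residual content of the removed formulation (ug).
#' @return Release fraction(s) in `[0, 1]`.
#' @examples
#' release_ratio(x_unused = 160, x_used = 49.6)
#' @export
release_ratio <- function(x_unused, x_used) {
  check_positive(x_unused = x_unused)
  if (any(x_used < 0)) abort("`x_used` cannot be negative.")
  if (any(x_used > x_unused)) {
    abort("Residual exceeds unused content: inconsistent assay values.")
  }
  (x_unused - x_used) / x_unused
}

#' Skin availability
#'
#' Fraction of the released drug that crosses the skin into the systemic
#' circulation: `F_skin = F / F_a`. Reported as a fraction; multiply by 100
#' for the percentage convention of summary tables.
#'
#' @param F_bio Transdermal bioavailability (fraction).
#' @param F_a Release fraction (fraction, must be positive).
#' @return Skin availability fraction(s).
#' @export
skin_availability <- function(F_bio, F_a) {
  if (any(!is.finite(F_a)) || any(F_a <= 0)) {
    abort("`F_a` must be positive: skin availability is undefined otherwise.")
  }
  if (any(F_bio < 0, na.rm = TRUE)) abort("`F_bio` cannot be negative.")
  F_bio / F_a
}

#' Per-subject bioavailability decomposition
#'
#' Joins transdermal NCA results to patch residual assays and computes the
#' full decomposition for every subject: `F` from the AUC ratio against the
#' group-mean IV AUC, `F_a` from the residuals, `F_skin = F / F_a`.
#'
#' @param td_results Tibble from [nca_td()] plus `body_weight_kg` and `dose`
#'   columns (or the raw columns `subject_id`, `AUC_0_inf`, `dose`,
#'   `body_weight_kg`).
#' @param residuals Tibble with `subject_id`, `x_unused_ug`, `x_used_ug`.
#' @param mean_auc_iv Group-mean IV `AUC_0_inf` (ng*hr/mL).
#' @param dose_iv IV dose (ug/kg).
#' @return Tibble with `subject_id`, `F`, `F_a`, `F_skin` (fractions).
#' @export
bioavailability_table <- function(td_results, residuals, mean_auc_iv, dose_iv) {
  need <- c("subject_id", "AUC_0_inf", "dose", "body_weight_kg")
  miss <- setdiff(need, names(td_results))
  if (length(miss)) abort(paste("`td_results` missing:", toString(miss)))
  td_results %>%
    left_join(residuals, by = "subject_id") %>%
    mutate(
      F = transdermal_F(.data$AUC_0_inf, .data$dose, .data$body_weight_kg,
                        mean_auc_iv, dose_iv),
      F_a = release_ratio(.data$x_unused_ug, .data$x_used_ug),
      F_skin = skin_availability(.data$F, .data$F_a)
    ) %>%
    select("subject_id", "F", "F_a", "F_skin")
}
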