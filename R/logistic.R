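# Univariate logistic screen and multivariate adjusted-odds-ratio model for
# the titration outcome. Fits are maximum-likelihood logistic regressions
# (stats::glm, binomial) with Wald confidence intervals and p-values, the
# convention of the clinical software the study design mirrors. Continuous
# covariates enter untransformed, so their odds ratios are per unit.

# Tight IRLS convergence so score equations hold to high precision.
glm_ctrl <- function() stats::glm.control(epsilon = 1e-12, maxit = 100)

# Backtick-quote a column name for use in a formula.
bt <- function(x) paste0("`", x, "`")

# Fit outcome ~ factors by ML logistic regression and return one tidy row
# per factor: OR, Wald 95% CI and p, with a separation flag when the Wald
# machinery degenerates (huge or non-finite standard error).
fit_logistic_wald <- function(data, outcome, factors, analysis) {
  fml <- stats::as.formula(
    paste(bt(outcome), "~", paste(bt(factors), collapse = " + ")))
  fit <- suppressWarnings(
    glm(fml, family = binomial(), data = data, control = glm_ctrl()))
  est <- coef(fit)[-1]
  se <- sqrt(diag(vcov(fit)))[-1]
  z <- qnorm(0.975)
  res <- tibble(
    factor = gsub("`", "", names(est)),
    OR = exp(unname(est)),
    CI95_low = exp(unname(est - z * se)),
    CI95_high = exp(unname(est + z * se)),
    p_value = 2 * pnorm(-abs(unname(est) / se)),
    analysis = analysis,
    n = stats::nobs(fit),
    separation_flag = !is.finite(se) | se > 10 | !fit$converged
  )
  attr(res, "model") <- fit
  res
}

#' Univariate logistic screen
#'
#' One single-predictor maximum-likelihood logistic fit of the binary
#' outcome per candidate factor, on complete cases for that factor. Factors
#' with Wald `p < alpha_screen` (and no separation flag) form the selected
#' set for the multivariate model, mirroring the p < 0.1 screening rule.
#' Zero-variance factors are skipped with a warning; separated fits are
#' returned flagged, never as silent estimates.
#'
#' @param cohort One row per patient; covariate and 0/1 indicator columns.
#' @param outcome Name of the 0/1 outcome column (default
#'   `"long_titration"`).
#' @param factors Character vector of candidate columns; default every
#'   column except `patient_id` and the outcome.
#' @param alpha_screen Screening threshold on the Wald p-value.
#' @return Tibble with one row per fitted factor (`factor`, `OR`,
#'   `CI95_low`, `CI95_high`, `p_value`, `analysis = "univariate"`, `n`,
#'   `separation_flag`) and attribute `"selected"` holding the selected
#'   factor names.
#' @export
univariate_screen <- function(cohort, outcome = "long_titration",
                              factors = NULL, alpha_screen = 0.1) {
  cohort <- as_tibble(cohort)
  if (!outcome %in% names(cohort)) abort("`outcome` column not found.")
  if (is.null(factors)) {
    factors <- setdiff(names(cohort), c("patient_id", outcome))
  }
  if (nrow(cohort) < 10) abort("Fewer than 10 subjects: screen not fitted.")

  res <- purrr::map(factors, function(f) {
    d <- cohort[stats::complete.cases(cohort[[f]]), , drop = FALSE]
    if (length(unique(d[[f]])) < 2) {
      warn(paste0("Skipping zero-variance factor `", f, "`."))
      return(NULL)
    }
    fit_logistic_wald(d, outcome, f, "univariate")
  }) %>% bind_rows()

  selected <- res$factor[res$p_value < alpha_screen & !res$separation_flag]
  attr(res, "selected") <- selected
  res
}

#' Multivariate adjusted odds ratios
#'
#' One joint maximum-likelihood logistic fit of the outcome on the selected
#' factors, on complete cases across all of them. Adjusted odds ratios are
#' `exp` of the joint coefficients with Wald 95% intervals; no
#' multiple-testing correction is applied. A selected set of size one
#' reduces exactly to the univariate fit.
#'
#' @inheritParams univariate_screen
#' @param selected_factors Non-empty character vector of factor columns
#'   (typically `attr(univariate_screen(...), "selected")`).
#' @return Tibble as in [univariate_screen()] with
#'   `analysis = "multivariate"` and the fitted `glm` in the `"model"`
#'   attribute.
#' @export
multivariate_aor <- function(cohort, outcome = "long_titration",
                             selected_factors) {
  if (length(selected_factors) == 0) abort("`selected_factors` is empty.")
  cohort <- as_tibble(cohort)
  cc <- stats::complete.cases(cohort[, selected_factors, drop = FALSE])
  fit_logistic_wald(cohort[cc, , drop = FALSE], outcome, selected_factors,
                    "multivariate")
}

#' Run the full titration analysis
#'
#' End-to-end clinical arm: extract titration periods from the daily
#' records, dichotomize at the cutoff, join the outcome to the covariate
#' table, run the univariate screen, and fit the multivariate
#' adjusted-odds-ratio model on the selected factors.
#'
#' @param cohort One row per patient: covariates plus 0/1 comorbidity
#'   columns.
#' @param records Daily records for [titration_period()].
#' @param factors Candidate factors for the screen; default every cohort
#'   column except `patient_id`.
#' @param alpha_screen Screening threshold (default 0.1).
#' @param cutoff Short/long period cutoff in days (default 5).
#' @param force_include Factors always carried into the multivariate model,
#'   screened in or not.
#' @param ... Passed to [titration_period()].
#' @return List of class `"titration_study"`: `$outcomes`, `$univariate`,
#'   `$selected`, `$multivariate`, `$n_censored`.
#' @examples
#' cs <- simulate_cohort(cohort_preset(n = 150), seed = 11)
#' ts <- titration_study(cs$cohort, cs$records, force_include = "E14")
#' ts$multivariate
#' @export
titration_study <- function(cohort, records, factors = NULL,
                            alpha_screen = 0.1, cutoff = 5,
                            force_include = NULL, ...) {
  outcomes <- dichotomize(titration_period(records, ...), cutoff = cutoff)
  data <- dplyr::inner_join(
    as_tibble(cohort),
    select(outcomes, "patient_id", "long_titration"),
    by = "patient_id")
  uni <- univariate_screen(data, "long_titration", factors, alpha_screen)
  selected <- union(attr(uni, "selected"), force_include)
  multi <- if (length(selected)) {
    multivariate_aor(data, "long_titration", selected)
  } else {
    NULL
  }
  structure(list(outcomes = outcomes, univariate = uni, selected = selected,
                 multivariate = multi,
                 n_censored = attr(outcomes, "n_censored")),
            class = "titration_study")
}

#' @export
print.titration_study <- function(x, ...) {
  cat(sprintf(
    "Titration study: %d patients analyzed (%d censored), %d long titrations\n",
    nrow(x$outcomes), x$n_censored, sum(x$outcomes$long_titration)))
  cat("Selected factors:", toString(x$selected), "\n")
  if (!is.null(x$multivariate)) {
    print(as_tibble(x$multivariate), n = Inf)
  }
  invisible(x)
}
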