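# Closed-form one-compartment concentration equations.
# Units are fixed package-wide: time in hours, concentration in ng/mL.
# IV doses are per-kg (ug/kg) against a per-kg volume (L/kg); transdermal
# doses are total ug against an absolute volume (L). In both cases ug/L is
# numerically ng/mL, so no conversion factor appears.

#' One-compartment IV bolus concentration
#'
#' Concentration at time `t` after an intravenous bolus, assuming
#' instantaneous distribution into a single compartment with first-order
#' elimination: `C(t) = (dose / Vd) * exp(-k_e * t)`.
#'
#' @param t Time after dosing (hours); vectorised, must be `>= 0`.
#' @param dose IV bolus dose (ug/kg body weight).
#' @param k_e First-order elimination rate constant (1/hr).
#' @param Vd Volume of distribution (L/kg).
#'
#' @return Numeric vector of plasma concentrations (ng/mL).
#' @examples
#' iv_bolus_concentration(c(0, 1, 5), dose = 10, k_e = 0.279, Vd = 6.49)
#' @export
iv_bolus_concentration <- function(t, dose, k_e, Vd) {
  check_positive(dose = dose, k_e = k_e, Vd = Vd)
  if (any(t < 0)) abort("`t` must be non-negative.")
  (dose / Vd) * exp(-k_e * t)
}

#' One-compartment first-order absorption (Bateman) concentration
#'
#' Concentration after application of a depot dose absorbed by first-order
#' kinetics into a one-compartment system, the model used for transdermal
#' delivery. In the flip-flop regime (`k_a < k_e`, typical for patches) the
#' terminal phase reflects absorption, not elimination.
#'
#' Two depot semantics are available. With `dialect = "full_depot"` (default)
#' the whole absorbable amount `F * dose` behaves as a first-order depot for
#' all time and `removal_time` is ignored — the bioavailable fraction already
#' encodes whatever is never absorbed. With `dialect = "truncated_input"`
#' absorption stops at `removal_time`; afterwards the central compartment
#' decays mono-exponentially at `k_e` from its state at removal.
#'
#' When `k_a` and `k_e` coincide (relative difference below `1e-8`) the
#' analytic limit `C(t) = F * dose * k * t * exp(-k t) / Vd` is used, so the
#' curve is continuous across the degeneracy.
#'
#' @param t Time after application (hours); vectorised, `>= 0`.
#' @param dose Total amount applied (ug).
#' @param F_bio Bioavailable fraction in (0, 1].
#' @param k_a First-order absorption rate constant (1/hr).
#' @param k_e First-order elimination rate constant (1/hr).
#' @param Vd Absolute volume of distribution (L).
#' @param removal_time Patch removal time (hr), or `NULL`. Only used by the
#'   `"truncated_input"` dialect.
#' @param dialect `"full_depot"` or `"truncated_input"` (see Details).
#'
#' @return Numeric vector of plasma concentrations (ng/mL).
#' @examples
#' # Wistar-like flip-flop curve peaking near 10 h
#' bateman_concentration(c(1, 8, 12, 48), dose = 160, F_bio = 0.53,
#'                       k_a = 0.0228, k_e = 0.279, Vd = 6.49 * 0.305)
#' @export
bateman_concentration <- function(t, dose, F_bio, k_a, k_e, Vd,
                                  removal_time = NULL,
                                  dialect = c("full_depot", "truncated_input")) {
  dialect <- arg_match(dialect)
  check_positive(dose = dose, k_a = k_a, k_e = k_e, Vd = Vd)
  if (F_bio <= 0 || F_bio > 1) abort("`F_bio` must be in (0, 1].")
  if (any(t < 0)) abort("`t` must be non-negative.")

  conc <- bateman_core(t, dose * F_bio, k_a, k_e, Vd)

  if (dialect == "truncated_input" && !is.null(removal_time)) {
    if (removal_time <= 0) abort("`removal_time` must be positive.")
    post <- t > removal_time
    if (any(post)) {
      c_rm <- bateman_core(removal_time, dose * F_bio, k_a, k_e, Vd)
      conc[post] <- c_rm * exp(-k_e * (t[post] - removal_time))
    }
  }
  conc
}

# Bateman kernel on the absorbable amount; routes near-degenerate rate pairs
# to the L'Hopital limit form.
bateman_core <- function(t, amount, k_a, k_e, Vd) {
  if (abs(k_a - k_e) < 1e-8 * max(k_a, k_e)) {
    k <- (k_a + k_e) / 2
    amount * k * t * exp(-k * t) / Vd
  } else {
    amount * k_a / (Vd * (k_a - k_e)) * (exp(-k_e * t) - exp(-k_a * t))
  }
}

#' Time of the Bateman peak
#'
#' Analytic argmax of the full-depot curve, `ln(k_a / k_e) / (k_a - k_e)`
#' (or `1 / k` in the degenerate limit `k_a = k_e = k`).
#'
#' @inheritParams bateman_concentration
#' @return Peak time (hr).
#' @export
bateman_tmax <- function(k_a, k_e) {
  check_positive(k_a = k_a, k_e = k_e)
  if (abs(k_a - k_e) < 1e-8 * max(k_a, k_e)) {
    2 / (k_a + k_e)
  } else {
    log(k_a / k_e) / (k_a - k_e)
  }
}

check_positive <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (any(!is.finite(v)) || any(v <= 0)) {
      abort(paste0("`", nm, "` must be finite and strictly positive."))
    }
  }
  invisible(TRUE)
}

#' Validate a pharmacokinetic parameter set
#'
#' Checks positivity of rates, volume and clearance, that the bioavailable
#' fraction lies in (0, 1], and — when clearance, elimination rate and volume
#' are all present — their mutual consistency `k_e = CL_tot / Vd_ss`.
#' Moment analysis obtains `k_e` from the terminal slope but `Vd_ss` from
#' moments, so agreement is only approximate; the tolerance is therefore a
#' declared fraction, default 20%.
#'
#' @param params Named list or one-row data frame with any of `k_a`, `k_e`,
#'   `Vd_ss`, `CL_tot`, `F`, `body_weight`.
#' @param consistency_tol Allowed relative deviation of `k_e` from
#'   `CL_tot / Vd_ss`.
#' @return The parameters as a one-row tibble, invisibly errors otherwise.
#' @export
validate_pk_parameters <- function(params, consistency_tol = 0.2) {
  p <- as.list(params)
  for (nm in intersect(names(p), c("k_a", "k_e", "Vd_ss", "CL_tot", "body_weight"))) {
    do.call(check_positive, p[nm])
  }
  if (!is.null(p$F)) {
    if (p$F <= 0 || p$F > 1) abort("`F` must be in (0, 1].")
  }
  if (!is.null(p$CL_tot) && !is.null(p$Vd_ss) && !is.null(p$k_e)) {
    implied <- p$CL_tot / p$Vd_ss
    if (abs(p$k_e - implied) > consistency_tol * implied) {
      abort(sprintf(
        "k_e (%.4g) deviates from CL_tot/Vd_ss (%.4g) by more than %.0f%%.",
        p$k_e, implied, 100 * consistency_tol))
    }
  }
  invisible(as_tibble(p))
}
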