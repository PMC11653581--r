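# Model-independent moment analysis of sampled concentration-time profiles.
#
# Profiles are long tibbles with one row per sample:
#   subject_id, route ("iv_bolus" | "transdermal"), time_hr, conc_ng_ml,
#   dose (ug/kg for IV, total ug for transdermal), body_weight_kg.
# Times must be strictly increasing within a subject, with at least 3 samples.

#' Terminal log-linear slope of a concentration profile
#'
#' Ordinary least squares of `log(conc)` on time over the last `n_points`
#' samples; `lambda_z` is the negated slope. Trailing zero concentrations are
#' truncated first (below-quantification tail); a zero or negative
#' concentration inside the fitting window is an error. A non-positive
#' `lambda_z` (rising tail) is returned but flagged, never silently accepted.
#'
#' @param data Data frame with columns `time_hr` and `conc_ng_ml` for a
#'   single profile.
#' @param n_points Number of terminal samples to regress on (>= 3).
#' @return One-row tibble: `lambda_z` (1/hr), `r_squared_terminal`,
#'   `n_terminal_points`, `lambda_z_flagged`.
#' @examples
#' prof <- tibble::tibble(time_hr = 1:6, conc_ng_ml = 2 * exp(-0.279 * (1:6)))
#' terminal_slope(prof)
#' @export
terminal_slope <- function(data, n_points = 3) {
  if (n_points < 3) abort("`n_points` must be at least 3.")
  data <- arrange(as_tibble(data), .data$time_hr)
  data <- truncate_trailing_zeros(data)
  if (nrow(data) < n_points) abort("Fewer positive samples than `n_points`.")
  win <- tail(data, n_points)
  if (any(win$conc_ng_ml <= 0)) {
    abort("Zero or negative concentration inside the terminal window.")
  }
  fit <- lm(log(conc_ng_ml) ~ time_hr, data = win)
  slope <- unname(coef(fit)[2])
  # noise-free profiles fit exactly; the r^2 "perfect fit" notice is routine
  r2 <- suppressWarnings(summary(fit)$r.squared)
  tibble(
    lambda_z = -slope,
    r_squared_terminal = r2,
    n_terminal_points = n_points,
    # a tail that does not decline (slope >= 0, up to floating noise) cannot
    # support log-linear extrapolation
    lambda_z_flagged = !is.finite(slope) || -slope <= 1e-10
  )
}

truncate_trailing_zeros <- function(data) {
  pos <- which(data$conc_ng_ml > 0)
  if (length(pos) == 0) abort("Profile has no positive concentrations.")
  data[seq_len(max(pos)), , drop = FALSE]
}

# Area of one segment by the linear-up/log-down rule (or pure linear).
# Returns c(auc, aumc). Log interpolation is exact for mono-exponential
# decline; the matching first-moment integral is used for AUMC.
segment_moments <- function(t1, t2, c1, c2, method = "linuplogdown") {
  dt <- t2 - t1
  use_log <- method == "linuplogdown" && c1 > 0 && c2 > 0 && c2 < c1
  if (use_log) {
    k <- log(c1 / c2) / dt
    auc <- (c1 - c2) / k
    aumc <- (t1 * c1 - t2 * c2) / k + (c1 - c2) / k^2
  } else {
    auc <- dt * (c1 + c2) / 2
    aumc <- dt * (t1 * c1 + t2 * c2) / 2
  }
  c(auc, aumc)
}

#' Area under the curve and first-moment curve to infinity
#'
#' Trapezoidal AUC/AUMC over the sampled range with log-linear tail
#' extrapolation. Segments are integrated linear-up/log-down by default
#' (linear where the curve rises or touches zero, exact exponential where it
#' falls); the tail contributes `C_last / lambda_z` to AUC and
#' `C_last * t_last / lambda_z + C_last / lambda_z^2` to AUMC.
#'
#' For IV bolus profiles the origin is back-extrapolated: `C(0)` from a
#' log-linear extension of the first two samples (falling back to the first
#' observed concentration if they do not decline). For transdermal profiles
#' `C(0) = 0`.
#'
#' @inheritParams terminal_slope
#' @param lambda_z Terminal slope (1/hr), must be positive.
#' @param route `"iv_bolus"` or `"transdermal"` (controls the origin rule).
#' @param method `"linuplogdown"` (default) or `"linear"`.
#' @return One-row tibble with `AUC_0_inf`, `AUMC_0_inf`, `AUC_0_last`, `C0`.
#' @export
auc_aumc <- function(data, lambda_z, route = c("iv_bolus", "transdermal"),
                     method = c("linuplogdown", "linear")) {
  route <- arg_match(route)
  method <- arg_match(method)
  if (!is.finite(lambda_z) || lambda_z <= 0) {
    abort("`lambda_z` must be positive to extrapolate the tail.")
  }
  data <- arrange(as_tibble(data), .data$time_hr)
  data <- truncate_trailing_zeros(data)
  tt <- data$time_hr
  cc <- data$conc_ng_ml

  if (tt[1] > 0) {
    c0 <- if (route == "iv_bolus") back_extrapolate_c0(tt, cc) else 0
    tt <- c(0, tt)
    cc <- c(c0, cc)
  }
  c0 <- cc[1]

  auc <- aumc <- 0
  for (i in seq_len(length(tt) - 1)) {
    m <- segment_moments(tt[i], tt[i + 1], cc[i], cc[i + 1], method)
    auc <- auc + m[1]
    aumc <- aumc + m[2]
  }
  c_last <- cc[length(cc)]
  t_last <- tt[length(tt)]
  tibble(
    AUC_0_last = auc,
    AUC_0_inf = auc + c_last / lambda_z,
    AUMC_0_inf = aumc + c_last * t_last / lambda_z + c_last / lambda_z^2,
    C0 = c0
  )
}

back_extrapolate_c0 <- function(tt, cc) {
  if (length(cc) >= 2 && cc[1] > 0 && cc[2] > 0 && cc[2] < cc[1]) {
    slope <- (log(cc[2]) - log(cc[1])) / (tt[2] - tt[1])
    exp(log(cc[1]) - slope * tt[1])
  } else {
    cc[1]
  }
}

#' Moment analysis of IV bolus profiles
#'
#' Model-independent (non-compartmental) analysis per subject:
#' `CL_tot = dose / AUC` (per kg, since IV doses are per kg),
#' `MRT = AUMC / AUC`, `Vd_ss = CL_tot * MRT`, and `k_e` taken as the
#' terminal slope. Subjects whose terminal slope is flagged (non-declining
#' tail) keep the flag and report `NA` parameters.
#'
#' @param profiles Long profile tibble (see file header); only rows with
#'   `route == "iv_bolus"` are used.
#' @param n_terminal Samples in the terminal-slope window.
#' @param method Trapezoid dialect passed to [auc_aumc()].
#' @return Tibble, one row per subject: AUC/AUMC to infinity, `MRT`, `k_e`,
#'   `CL_tot` (L/hr/kg), `Vd_ss` (L/kg), terminal-fit diagnostics.
#' @export
nca_iv <- function(profiles, n_terminal = 3, method = "linuplogdown") {
  profiles <- filter(as_tibble(profiles), .data$route == "iv_bolus")
  if (nrow(profiles) == 0) abort("No IV bolus rows in `profiles`.")
  profiles %>%
    group_by(.data$subject_id) %>%
    dplyr::group_modify(~ nca_iv_one(.x, n_terminal, method)) %>%
    ungroup()
}

nca_iv_one <- function(data, n_terminal, method) {
  validate_profile(data)
  dose <- data$dose[1]
  ts <- terminal_slope(data, n_terminal)
  if (ts$lambda_z_flagged) {
    return(bind_cols_flat(ts, tibble(
      AUC_0_inf = NA_real_, AUMC_0_inf = NA_real_, MRT = NA_real_,
      k_e = NA_real_, CL_tot = NA_real_, Vd_ss = NA_real_, C0 = NA_real_
    )))
  }
  mom <- auc_aumc(data, ts$lambda_z, route = "iv_bolus", method = method)
  mrt <- mom$AUMC_0_inf / mom$AUC_0_inf
  cl <- dose / mom$AUC_0_inf
  bind_cols_flat(ts, tibble(
    AUC_0_inf = mom$AUC_0_inf, AUMC_0_inf = mom$AUMC_0_inf, MRT = mrt,
    k_e = ts$lambda_z, CL_tot = cl, Vd_ss = cl * mrt, C0 = mom$C0
  ))
}

#' Moment analysis of transdermal profiles
#'
#' Per subject: `C_max` and `T_max` by direct scan of the sampled points
#' (earliest time on ties), AUC to infinity as in [auc_aumc()] with
#' `C(0) = 0`, and apparent clearance
#' `CL_tot/F = (dose / body_weight) / AUC_0_inf` (transdermal doses are total
#' ug, so body weight converts to per-kg clearance).
#'
#' @inheritParams nca_iv
#' @return Tibble, one row per subject: `C_max`, `T_max`, `AUC_0_inf`,
#'   `CL_tot_over_F`, terminal-fit diagnostics.
#' @export
nca_td <- function(profiles, n_terminal = 3, method = "linuplogdown") {
  profiles <- filter(as_tibble(profiles), .data$route == "transdermal")
  if (nrow(profiles) == 0) abort("No transdermal rows in `profiles`.")
  profiles %>%
    group_by(.data$subject_id) %>%
    dplyr::group_modify(~ nca_td_one(.x, n_terminal, method)) %>%
    ungroup()
}

nca_td_one <- function(data, n_terminal, method) {
  validate_profile(data)
  data <- arrange(data, .data$time_hr)
  i_max <- which.max(data$conc_ng_ml)  # which.max takes the earliest tie
  ts <- terminal_slope(data, n_terminal)
  if (ts$lambda_z_flagged) {
    return(bind_cols_flat(ts, tibble(
      C_max = data$conc_ng_ml[i_max], T_max = data$time_hr[i_max],
      AUC_0_inf = NA_real_, CL_tot_over_F = NA_real_,
      dose = data$dose[1], body_weight_kg = data$body_weight_kg[1]
    )))
  }
  mom <- auc_aumc(data, ts$lambda_z, route = "transdermal", method = method)
  dose_per_kg <- data$dose[1] / data$body_weight_kg[1]
  bind_cols_flat(ts, tibble(
    C_max = data$conc_ng_ml[i_max], T_max = data$time_hr[i_max],
    AUC_0_inf = mom$AUC_0_inf, CL_tot_over_F = dose_per_kg / mom$AUC_0_inf,
    dose = data$dose[1], body_weight_kg = data$body_weight_kg[1]
  ))
}

validate_profile <- function(data) {
  need <- c("time_hr", "conc_ng_ml", "dose")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(paste("Profile is missing columns:", toString(miss)))
  if (nrow(data) < 3) abort("Profile needs at least 3 samples.")
  if (any(diff(data$time_hr[order(data$time_hr)]) <= 0)) {
    abort("Sample times must be strictly increasing within a subject.")
  }
  if (any(!is.finite(data$conc_ng_ml)) || any(data$conc_ng_ml < 0)) {
    abort("Concentrations must be finite and non-negative.")
  }
  invisible(data)
}

bind_cols_flat <- function(a, b) as_tibble(c(as.list(b), as.list(a)))
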