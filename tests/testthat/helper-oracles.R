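# Independent oracles and fixture builders used across the suite.

# Exhaustive window scan for the titration rule: checks every
# `stability_days` window directly, independent of the vectorised
# implementation under test.
brute_titration <- function(dose, rescue, stability_days = 5, rescue_max = 3) {
  n <- length(dose)
  if (n < stability_days) stop("record too short")
  for (T in stability_days:n) {
    win <- (T - stability_days + 1):T
    if (length(unique(dose[win])) == 1 && all(rescue[win] <= rescue_max)) {
      return(as.integer(T))
    }
  }
  NA_integer_
}

# Random daily record with dose switches and unconstrained rescue counts.
random_record <- function(id, len) {
  n_seg <- sample(1:4, 1)
  seg_len <- as.vector(stats::rmultinom(1, len - n_seg, rep(1, n_seg))) + 1
  dose <- rep(sample(c(0.5, 1, 2, 4), n_seg, replace = TRUE), seg_len)
  tibble::tibble(
    patient_id = id,
    day = seq_len(len),
    dose_mg = dose,
    rescue_count = sample(0:6, len, replace = TRUE)
  )
}

# Adaptive-quadrature AUC of a concentration function on [0, upper].
quad_auc <- function(f, upper) {
  stats::integrate(f, 0, upper, rel.tol = 1e-10, subdivisions = 500L)$value
}

# Dense noise-free IV profile tibble (single subject).
dense_iv_profile <- function(dose = 10, k_e = 0.255, Vd = 6.94,
                             n = 250, half_lives = 10) {
  tt <- seq(0.01, half_lives * log(2) / k_e, length.out = n)
  tibble::tibble(
    subject_id = "iv1", route = "iv_bolus", time_hr = tt,
    conc_ng_ml = iv_bolus_concentration(tt, dose, k_e, Vd),
    dose = dose, body_weight_kg = 0.3
  )
}

# Noise-free transdermal profile at the study's 8-point schedule.
schedule_td_profile <- function(k_a, k_e, Vd_ss = 6.94, bw = 0.339,
                                F_bio = 0.555, dose = 160) {
  tt <- c(1, 2, 4, 8, 12, 24, 30, 48)
  tibble::tibble(
    subject_id = "td1", route = "transdermal", time_hr = tt,
    conc_ng_ml = bateman_concentration(tt, dose, F_bio, k_a, k_e, Vd_ss * bw),
    dose = dose, body_weight_kg = bw
  )
}

# Expand 2x2 counts (exposed/unexposed x outcome) into a patient table.
expand_2x2 <- function(a, b, c_, d) {
  # a: exposed & outcome1, b: exposed & outcome0,
  # c_: unexposed & outcome1, d: unexposed & outcome0
  tibble::tibble(
    x = c(rep(1, a + b), rep(0, c_ + d)),
    y = c(rep(1, a), rep(0, b), rep(1, c_), rep(0, d))
  )
}
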