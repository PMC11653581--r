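# Flip-flop absorption-rate estimation. Only k_a is free: the elimination
# rate and volume come from the same subject's IV moment analysis and the
# bioavailable fraction from the AUC ratio, mirroring how a transdermal
# profile is fit once the IV arm has pinned down disposition.

#' Fit the absorption rate constant of a transdermal profile
#'
#' Minimises the weighted least-squares objective
#' `sum(w_i * (C_obs_i - C_model(t_i; k_a))^2)` over `k_a` alone, with the
#' subject's `F`, `k_e` and absolute `Vd` held fixed at their IV-derived /
#' AUC-derived values. The search is bounded to (1e-5, 100) 1/hr: a
#' deterministic log-spaced scan brackets the minimum and golden-section
#' refinement polishes it, so the fit has no random component. The starting
#' bracket is centred on the moment-matching initial value from
#' [ka_init_from_tmax()].
#'
#' @param data Data frame with `time_hr`, `conc_ng_ml` for one transdermal
#'   profile.
#' @param dose Total applied amount (ug).
#' @param F_bio Subject's bioavailable fraction (from the AUC ratio). A
#'   noisy estimate above 1 is accepted with a warning — the fit only needs
#'   the absorbable amount `dose * F_bio`.
#' @param k_e Elimination rate constant (1/hr), IV-derived.
#' @param Vd Absolute volume of distribution (L), IV-derived (`Vd_ss` per kg
#'   times body weight).
#' @param weighting `"uniform"` (default), `"one_over_c"` or
#'   `"one_over_c2"` residual weights; weights use the observed
#'   concentrations with a small floor to tolerate zeros.
#' @param scale Fit on the `"linear"` (default) or `"log"` concentration
#'   scale; the log scale drops zero observations.
#' @param dialect Depot semantics passed to [bateman_concentration()].
#' @param removal_time Patch removal time (hr), used only by the
#'   `"truncated_input"` dialect.
#' @return Object of class `"ka_fit"`: a list with `k_a`,
#'   `residual_sum_squares`, `n_observations`, `converged`, `weighting`,
#'   `flip_flop` (`k_a < k_e`), `half_life_apparent` (hr), the fixed
#'   parameters, and the data. `tidy()` and `glance()` methods are provided.
#' @examples
#' tt <- c(1, 2, 4, 8, 12, 24, 30, 48)
#' cc <- bateman_concentration(tt, 160, 0.555, 0.0317, 0.255, 6.94 * 0.339)
#' fit <- fit_ka(tibble::tibble(time_hr = tt, conc_ng_ml = cc),
#'               dose = 160, F_bio = 0.555, k_e = 0.255, Vd = 6.94 * 0.339)
#' fit$k_a
#' @export
fit_ka <- function(data, dose, F_bio, k_e, Vd,
                   weighting = c("uniform", "one_over_c", "one_over_c2"),
                   scale = c("linear", "log"),
                   dialect = c("full_depot", "truncated_input"),
                   removal_time = NULL) {
  weighting <- arg_match(weighting)
  scale <- arg_match(scale)
  dialect <- arg_match(dialect)
  check_positive(dose = dose, F_bio = F_bio, k_e = k_e, Vd = Vd)
  if (F_bio > 1) {
    warn("Estimated F above 1 used as-is in the absorption fit.")
  }

  data <- arrange(as_tibble(data), .data$time_hr)
  tt <- data$time_hr
  cc <- data$conc_ng_ml
  if (all(cc <= 0)) abort("All-zero profile: nothing to fit.")
  if (scale == "log") {
    keep <- cc > 0
    tt <- tt[keep]; cc <- cc[keep]
  }

  w <- switch(weighting,
    uniform = rep(1, length(cc)),
    one_over_c = 1 / pmax(cc, 1e-6),
    one_over_c2 = 1 / pmax(cc, 1e-6)^2
  )
  objective <- function(log_ka) {
    pred <- bateman_concentration(tt, dose * F_bio, 1, exp(log_ka), k_e, Vd,
                                  removal_time = removal_time,
                                  dialect = dialect)
    if (scale == "log") {
      pred <- pmax(pred, 1e-12)
      sum(w * (log(cc) - log(pred))^2)
    } else {
      sum(w * (cc - pred)^2)
    }
  }

  t_max_obs <- tt[which.max(cc)]
  ka0 <- ka_init_from_tmax(t_max_obs, k_e)
  lo <- log(1e-5); hi <- log(100)
  grid <- sort(unique(c(seq(lo, hi, length.out = 80), log(ka0))))
  vals <- vapply(grid, objective, numeric(1))
  i <- which.min(vals)
  bracket <- c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)])
  opt <- optimize(objective, interval = bracket, tol = 1e-10)

  k_a <- exp(opt$minimum)
  rss <- if (scale == "log") {
    pred <- bateman_concentration(tt, dose * F_bio, 1, k_a, k_e, Vd,
                                  removal_time = removal_time, dialect = dialect)
    sum(w * (cc - pred)^2)
  } else {
    opt$objective
  }
  structure(list(
    k_a = k_a,
    residual_sum_squares = rss,
    n_observations = length(cc),
    converged = is.finite(opt$objective),
    weighting = weighting,
    scale = scale,
    dialect = dialect,
    flip_flop = k_a < k_e,
    half_life_apparent = log(2) / min(k_a, k_e),
    F_bio = F_bio, k_e = k_e, Vd = Vd, dose = dose,
    data = tibble(time_hr = tt, conc_ng_ml = cc)
  ), class = "ka_fit")
}

#' Initial absorption rate from the observed peak time
#'
#' Solves the Bateman argmax relation
#' `T_max = ln(k_a / k_e) / (k_a - k_e)` for `k_a` on the flip-flop branch
#' `k_a < k_e` by bisection. When no solution exists on that branch (the
#' observed peak is earlier than `1 / k_e`, where the relation has no
#' slow-absorption root), falls back to `k_e / 10`.
#'
#' @param t_max_obs Observed peak time (hr).
#' @param k_e Elimination rate constant (1/hr).
#' @return Initial `k_a` estimate (1/hr).
#' @export
ka_init_from_tmax <- function(t_max_obs, k_e) {
  check_positive(t_max_obs = t_max_obs, k_e = k_e)
  f <- function(ka) bateman_tmax(ka, k_e) - t_max_obs
  lo <- 1e-6 * k_e
  hi <- (1 - 1e-6) * k_e
  if (f(lo) * f(hi) > 0) return(k_e / 10)
  uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Flip-flop diagnostics for a rate-constant pair
#'
#' Flip-flop absorption means the absorption rate is the slower process
#' (`k_a < k_e`, strict), in which case the apparent terminal half-life of
#' the profile is `ln(2) / k_a` rather than the elimination half-life.
#'
#' @param k_a,k_e Absorption and elimination rate constants (1/hr).
#' @return One-row tibble: `flip_flop`, `half_life_apparent` (hr),
#'   `rate_limiting` (`"absorption"` or `"elimination"`).
#' @examples
#' flipflop_check(k_a = 0.0228, k_e = 0.279)
#' @export
flipflop_check <- function(k_a, k_e) {
  check_positive(k_a = k_a, k_e = k_e)
  tibble(
    k_a = k_a, k_e = k_e,
    flip_flop = k_a < k_e,
    half_life_apparent = log(2) / min(k_a, k_e),
    rate_limiting = if (k_a < k_e) "absorption" else "elimination"
  )
}

#' Fit k_a for every subject of a transdermal profile table
#'
#' Convenience wrapper over [fit_ka()]: joins per-subject fixed parameters
#' (columns `subject_id`, `F_bio`, `k_e`, `Vd`) to the long profile table and
#' returns one tidy row per subject.
#'
#' @param profiles Long profile tibble, transdermal rows.
#' @param subject_params Tibble with `subject_id`, `F_bio`, `k_e`, `Vd`.
#' @param ... Passed to [fit_ka()].
#' @return Tibble with the [tidy.ka_fit()] columns per subject.
#' @export
fit_ka_cohort <- function(profiles, subject_params, ...) {
  profiles <- filter(as_tibble(profiles), .data$route == "transdermal")
  split(profiles, profiles$subject_id) %>%
    purrr::imap(function(d, id) {
      p <- filter(subject_params, .data$subject_id == id)
      if (nrow(p) != 1) abort(paste("No unique parameters for subject", id))
      if (anyNA(c(p$F_bio, p$k_e, p$Vd))) {
        # upstream flagged results (e.g. a non-declining tail) propagate as
        # an unfit subject rather than an error
        return(tibble(subject_id = id, k_a = NA_real_, flip_flop = NA,
                      half_life_apparent = NA_real_,
                      residual_sum_squares = NA_real_, converged = FALSE))
      }
      fit <- fit_ka(d, dose = d$dose[1], F_bio = p$F_bio, k_e = p$k_e,
                    Vd = p$Vd, ...)
      mutate(tidy(fit), subject_id = id, .before = 1)
    }) %>%
    bind_rows()
}

#' @export
print.ka_fit <- function(x, ...) {
  cat("One-compartment absorption fit (", x$dialect, ")\n", sep = "")
  cat(sprintf("  k_a = %.4g /hr  (fixed: k_e = %.4g, Vd = %.4g L, F = %.3f)\n",
              x$k_a, x$k_e, x$Vd, x$F_bio))
  cat(sprintf("  RSS = %.4g on %d observations (%s weights)\n",
              x$residual_sum_squares, x$n_observations, x$weighting))
  cat(sprintf("  flip-flop: %s; apparent half-life %.1f hr\n",
              x$flip_flop, x$half_life_apparent))
  invisible(x)
}

#' Tidy a k_a fit
#' @method tidy ka_fit
#' @param x A `"ka_fit"` object.
#' @param ... Unused.
#' @return One-row tibble with the estimate and diagnostics.
#' @export
tidy.ka_fit <- function(x, ...) {
  tibble(
    k_a = x$k_a,
    flip_flop = x$flip_flop,
    half_life_apparent = x$half_life_apparent,
    residual_sum_squares = x$residual_sum_squares,
    converged = x$converged
  )
}

#' Glance at a k_a fit
#' @method glance ka_fit
#' @param x A `"ka_fit"` object.
#' @param ... Unused.
#' @return One-row tibble with fit-level summaries.
#' @export
glance.ka_fit <- function(x, ...) {
  tibble(
    n_observations = x$n_observations,
    residual_sum_squares = x$residual_sum_squares,
    weighting = x$weighting,
    scale = x$scale,
    dialect = x$dialect,
    converged = x$converged
  )
}
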