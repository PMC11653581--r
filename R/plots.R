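# ggplot2 graphics for the package's result types.

#' Plot concentration-time profiles
#'
#' Spaghetti plot of sampled profiles, one line per animal, facetted by
#' route (the IV and transdermal time scales differ by two orders of
#' magnitude). A log concentration axis shows the terminal log-linear phase
#' — and the flip-flop difference between routes — most clearly.
#'
#' @param profiles Long profile tibble.
#' @param log_y Log10 concentration axis (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles, log_y = TRUE) {
  p <- ggplot2::ggplot(
    filter(as_tibble(profiles), .data$conc_ng_ml > 0),
    ggplot2::aes(x = .data$time_hr, y = .data$conc_ng_ml,
                 group = .data$subject_id,
                 colour = if ("strain" %in% names(profiles)) .data$strain else NULL)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~route, scales = "free_x") +
    ggplot2::labs(x = "Time (hr)", y = "Concentration (ng/mL)",
                  colour = "strain") +
    ggplot2::theme_bw()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot an absorption-rate fit
#'
#' Observed transdermal samples with the fitted one-compartment absorption
#' curve overlaid.
#'
#' @param object A `"ka_fit"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ka_fit
#' @export
autoplot.ka_fit <- function(object, ...) {
  tt <- seq(0, max(object$data$time_hr) * 1.05, length.out = 200)
  curve <- tibble(
    time_hr = tt,
    conc_ng_ml = bateman_concentration(tt, object$dose * object$F_bio, 1,
                                       object$k_a, object$k_e, object$Vd,
                                       dialect = object$dialect))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time_hr, y = .data$conc_ng_ml)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Time (hr)", y = "Concentration (ng/mL)",
      title = sprintf("k_a = %.3g /hr (%s)", object$k_a,
                      if (object$flip_flop) "flip-flop" else "absorption-fast")) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the titration-period distribution
#'
#' Histogram of extracted titration periods, coloured by the short/long
#' grouping.
#'
#' @param outcomes Tibble from [dichotomize()].
#' @return A ggplot object.
#' @export
plot_titration_distribution <- function(outcomes) {
  ggplot2::ggplot(outcomes,
                  ggplot2::aes(x = .data$titration_period,
                               fill = .data$group)) +
    ggplot2::geom_histogram(binwidth = 1, colour = "grey30") +
    ggplot2::labs(x = "Titration period (days)", y = "Patients",
                  fill = NULL) +
    ggplot2::theme_bw()
}

#' Forest plot of odds ratios
#'
#' Point estimates and 95% Wald intervals from the univariate screen and/or
#' the multivariate model, on a log odds-ratio axis.
#'
#' @param results Tibble from [univariate_screen()] or
#'   [multivariate_aor()], or both row-bound.
#' @return A ggplot object.
#' @export
plot_odds_ratios <- function(results) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$OR, y = .data$factor,
                               colour = .data$analysis)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$CI95_low, xmax = .data$CI95_high),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL, colour = NULL) +
    ggplot2::theme_bw()
}
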