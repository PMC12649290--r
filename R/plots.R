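#' Plot a concentration-time profile
#'
#' @param profile A `pk_profile` tibble.
#' @param window Optional length-2 therapeutic window (ug/L) drawn as dashed
#'   lines on the parent panel.
#' @param object,x,... `autoplot()` compatibility arguments.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, window = NULL) {
  stopifnot(is.data.frame(profile))
  long <- tidyr::pivot_longer(profile, dplyr::all_of(c("conc_parent", "conc_metab")),
                              names_to = "analyte", values_to = "conc",
                              names_prefix = "conc_")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$conc)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "Time (h)", y = "Concentration (µg/L)")
  if (!is.null(window)) {
    p <- p + ggplot2::geom_hline(
      data = data.frame(analyte = "parent", y = window),
      ggplot2::aes(yintercept = .data$y), linetype = "dashed")
  }
  p
}

#' @rdname plot_profile
#' @exportS3Method ggplot2::autoplot
autoplot.pk_profile <- function(object, ...) plot_profile(object, ...)

#' Plot a prediction-corrected visual predictive check
#'
#' Observed 5th/50th/95th percentile lines over the simulated 90% CI bands,
#' per analyte and time-after-dose bin.
#'
#' @param x A `pk_pcvpc` object from [pk_pcvpc()].
#' @param object,... `autoplot()` compatibility arguments.
#' @return A ggplot object.
#' @export
plot_pcvpc <- function(x) {
  ggplot2::ggplot(x, ggplot2::aes(.data$t_mid, group = .data$percentile)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_lo, ymax = .data$sim_hi),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed,
                                    linetype = factor(.data$percentile))) +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "Time after dose (h)",
                  y = "Prediction-corrected concentration (µg/L)",
                  linetype = "Observed percentile")
}

#' @rdname plot_pcvpc
#' @exportS3Method ggplot2::autoplot
autoplot.pk_pcvpc <- function(object, ...) plot_pcvpc(object)

#' Plot normalized prediction distribution errors
#'
#' @param x A `pk_npde` object from [pk_npde()].
#' @param object,... `autoplot()` compatibility arguments.
#' @return A ggplot object.
#' @export
plot_npde <- function(x) {
  ggplot2::ggplot(x, ggplot2::aes(.data$time, .data$npde)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(-2, 0, 2), linetype = "dashed") +
    ggplot2::facet_wrap(~analyte) +
    ggplot2::labs(x = "Time (h)", y = "NPDE")
}

#' @rdname plot_npde
#' @exportS3Method ggplot2::autoplot
autoplot.pk_npde <- function(object, ...) plot_npde(object)

#' Plot simulated exposure-metric distributions across regimens
#'
#' @param metrics Tibble from [pk_simulate_cohort()] or [pk_crossover()].
#' @param metric One of `"auc_0_144"`, `"c_max"`, `"c_min"`.
#' @param analyte `"parent"` or `"metab"`.
#' @return A ggplot object.
#' @export
plot_exposure <- function(metrics, metric = "auc_0_144", analyte = "parent") {
  d <- dplyr::filter(metrics, .data$analyte == !!analyte)
  ggplot2::ggplot(d, ggplot2::aes(.data[[metric]], fill = .data$regimen)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::labs(x = metric, y = "Density", fill = "Regimen")
}
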