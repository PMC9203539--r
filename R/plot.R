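# ggplot2 displays for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a tympanogram
#'
#' Admittance versus ear-canal pressure in the conventional orientation
#' (positive pressure to the right).
#'
#' @param object A [tympanogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tympanogram <- function(object, ...) {
  calibrated <- isTRUE(attr(object, "calibrated"))
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$pressure_daPa, y = .data$admittance_mL)) +
    ggplot2::geom_line(linewidth = 0.7, colour = "#2C6E91") +
    ggplot2::labs(x = "Ear canal pressure (daPa)",
                  y = if (calibrated) "Admittance (mL)" else "Amplitude (a.u.)",
                  title = "Tympanogram") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.tympanogram
#' @param t A [tympanogram()].
#' @param metrics Optional [tymp_metrics()] to annotate the peak.
#' @export
plot_tympanogram <- function(t, metrics = NULL) {
  p <- autoplot.tympanogram(t)
  if (!is.null(metrics) && !isTRUE(metrics$is_flat))
    p <- p + ggplot2::annotate(
      "point", x = metrics$peak_pressure,
      y = metrics$peak_admittance_absolute, colour = "#B4452C", size = 2)
  p
}

#' Bland-Altman plot
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot with the bias (solid) and 95% limits (dotted).
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = object$limits, linetype = "dotted") +
    ggplot2::labs(x = "Mean of devices", y = "Difference (device2 - device1)",
                  title = sprintf("Bland-Altman: bias %.3g, limits [%.3g, %.3g]",
                                  object$bias, object$limits[1], object$limits[2])) +
    ggplot2::theme_minimal()
}

#' Plot a band-limited envelope
#'
#' @param object A [compute_envelope()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tymp_envelope <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$frame_time, y = .data$level)) +
    ggplot2::geom_line(colour = "#2C6E91") +
    ggplot2::labs(x = "Time (s)", y = "Band-limited RMS (full scale)",
                  title = "Probe-tone envelope (220-230 Hz)") +
    ggplot2::theme_minimal()
}
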