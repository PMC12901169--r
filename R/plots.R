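#' Plot a worst-case error phase sweep
#'
#' Error-versus-phase curve: underestimation in percent of the actual value
#' over the reference-plane phase offset, with the peak marked.
#'
#' @param object A `"phase_sweep_result"` from [phase_sweep()] or
#'   [power_error_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phase_sweep_result
#' @export
autoplot.phase_sweep_result <- function(object, ...) {
  df <- object$sweep
  what <- if (object$kind == "power") "total forward power" else "local SAR"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase_rad,
                                   y = .data$percent_of_actual)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point(
      data = df[which.max(df$ratio), , drop = FALSE],
      colour = "#d95f02", size = 2) +
    ggplot2::scale_x_continuous(
      breaks = seq(0, 2 * pi, by = pi / 2),
      labels = c("0", "π/2", "π", "3π/2", "2π"),
      limits = c(0, 2 * pi)) +
    ggplot2::labs(
      x = "reference-plane phase offset φ (rad)",
      y = "underestimation (% of actual)",
      title = sprintf("Worst-case underestimation of %s", what),
      subtitle = sprintf("directivity %s dB; peak %.2f%% at φ = %.2f rad",
                         paste(format(object$directivity_db), collapse = "/"),
                         object$peak_percent_of_actual,
                         object$peak_phase_rad)) +
    ggplot2::theme_minimal()
}

#' Plot a reflected-power spectrum
#'
#' Eigenvalues of \eqn{S^H S} by mode index: the worst-case reflected power
#' fraction per orthogonal excitation mode.
#'
#' @param object A `"passivity_spectrum"` from [reflected_power_spectrum()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot passivity_spectrum
#' @export
autoplot.passivity_spectrum <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode,
                                   y = .data$reflected_power_fraction)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::scale_x_continuous(breaks = df$mode) +
    ggplot2::labs(x = "mode", y = "reflected power fraction",
                  title = "Eigenvalues of SᴴS",
                  subtitle = sprintf("worst-case total reflected power %.1f%%",
                                     100 * object$eigenvalues[1])) +
    ggplot2::theme_minimal()
}
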