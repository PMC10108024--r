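#' Plot a velocity waveform
#'
#' @param object A `vel_waveform`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vel_waveform <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time,
                                       y = .data$velocity)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3,
                        colour = "grey60") +
    ggplot2::geom_line(colour = "#2c7fb8", linewidth = 0.7) +
    ggplot2::geom_point(size = 0.6, colour = "#2c7fb8") +
    ggplot2::labs(x = "time (s)", y = "velocity (m/s)",
                  title = wf_label(object),
                  subtitle = sprintf("%s velocity, period %.3g s",
                                     wf_mode(object), wf_period(object))) +
    ggplot2::theme_minimal()
}

#' Plot a wall shear stress series
#'
#' For a single series, `tau_w(t)` over the cycle; for a [wss_analysis()]
#' fit, both methods overlaid.
#'
#' @param object A `wss_series` or `wss_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wss_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$wss)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3,
                        colour = "grey60") +
    ggplot2::geom_line(colour = "#d95f02", linewidth = 0.7) +
    ggplot2::labs(x = "time (s)", y = "wall shear stress (Pa)",
                  title = attr(object, "method")) +
    ggplot2::theme_minimal()
}

#' Plot a radial velocity profile
#'
#' Velocity-versus-radius snapshots at a handful of instants across the
#' cycle (default 8), the standard way of visualising how the profile
#' blunts and phase-lags as the Womersley number grows.
#'
#' @param object A `flow_profile`.
#' @param times Instants to draw; defaults to 8 evenly spaced snapshots.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.flow_profile <- function(object, times = NULL, ...) {
  tg <- attr(object, "t_grid")
  times <- times %||% tg[seq(1, length(tg),
                             length.out = min(8, length(tg)))]
  pick <- vapply(times, function(t) tg[which.min(abs(tg - t))], numeric(1))
  df <- dplyr::filter(object, .data$time %in% pick)
  df$time_lab <- sprintf("t = %.3f s", df$time)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r * 1e3,
                                   y = .data$velocity,
                                   colour = .data$time_lab)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3,
                        colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "r (mm)", y = "velocity (m/s)", colour = NULL,
                  title = sprintf("%s profile", profile_method(object))) +
    ggplot2::theme_minimal()
}
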