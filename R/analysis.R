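#' Reconstruct and compare pulsatile wall shear stress
#'
#' The one-stop analysis: Fourier-decomposes a velocity waveform, evaluates
#' the velocity-driven Womersley reconstruction and/or the quasi-steady
#' Poiseuille comparator on a common time grid, and summarises wall shear
#' stress per method.  With `method = "both"` the Poiseuille-vs-Womersley
#' comparison percentages are included.
#'
#' @inheritParams womersley_profile
#' @param method `"womersley"`, `"poiseuille"` or `"both"`.
#' @param n_time Time samples per cycle for the output series.
#'
#' @return An object of class `wss_fit`: a list with elements `waveform`,
#'   `spectrum`, `vessel`, `alpha` (Womersley number), `reynolds`
#'   (advisory Reynolds number `2 R U rho / mu`), `wss` (long tibble:
#'   `method`, `time`, `wss`), `flow`, `summary` (row per method) and
#'   `comparison` (or `NULL`).  Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' fit <- wss_analysis(synth_template("brachial_like"),
#'                     template_vessel("brachial_like"))
#' tidy(fit)
#' glance(fit)
#' @export
wss_analysis <- function(w, vessel, method = c("both", "womersley",
                                               "poiseuille"),
                         n_harmonics = 20L, n_time = 200L) {
  method <- match.arg(method)
  stopifnot(inherits(vessel, "vessel_spec"))
  s_raw <- if (inherits(w, "fourier_spectrum")) w else
    fourier_spectrum(w, n_harmonics = n_harmonics)
  time <- default_time_grid(sp_period(s_raw), n_time)
  methods <- if (method == "both") c("poiseuille", "womersley") else method
  wss <- list()
  flow <- list()
  summaries <- list()
  for (m in methods) {
    series <- switch(m,
      womersley = womersley_wss(s_raw, vessel, time = time),
      poiseuille = poiseuille_wss(s_raw, vessel, time = time))
    q <- switch(m,
      womersley = womersley_flow(s_raw, vessel, time = time),
      poiseuille = poiseuille_flow(s_raw, vessel, time = time))
    wss[[m]] <- dplyr::mutate(as_tibble(series), method = m,
                              .before = 1)
    flow[[m]] <- dplyr::mutate(as_tibble(q), method = m, .before = 1)
    summaries[[m]] <- wss_summary(series)
  }
  comparison <- if (method == "both") {
    compare_methods(summaries$poiseuille, summaries$womersley)
  }
  s_mean <- if (sp_mode(s_raw) == "centerline") {
    centerline_to_mean(s_raw, vessel)
  } else {
    s_raw
  }
  b0 <- Re(s_mean$b[s_mean$n == 0])
  structure(list(
    waveform = if (inherits(w, "vel_waveform")) w,
    spectrum = s_mean,
    vessel = vessel,
    alpha = womersley_number(vessel, omega = sp_omega(s_raw)),
    reynolds = reynolds_number(vessel, b0),
    n_harmonics = max(s_raw$n),
    wss = dplyr::bind_rows(wss),
    flow = dplyr::bind_rows(flow),
    summary = dplyr::bind_rows(summaries),
    comparison = comparison),
    class = "wss_fit")
}

#' @export
print.wss_fit <- function(x, ...) {
  cat(sprintf(
    "<wss_fit> alpha = %.3g, Re = %.0f, N = %d harmonics, methods: %s\n",
    x$alpha, x$reynolds, x$n_harmonics,
    paste(unique(x$summary$method), collapse = ", ")))
  if (x$reynolds > 2000) {
    cat("  note: Re > 2000; the laminar-flow assumption may not hold\n")
  }
  print(x$summary)
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

#' Tidy a wall shear stress fit
#'
#' @param x A [wss_analysis()] result.
#' @param ... Unused.
#' @return The per-method summary tibble (one row per method with peak,
#'   minimum, cycle-mean, time-median WSS and OSI).
#' @export
tidy.wss_fit <- function(x, ...) {
  as_tibble(x$summary)
}

#' Glance at a wall shear stress fit
#'
#' @param x A [wss_analysis()] result.
#' @param ... Unused.
#' @return A one-row tibble: `alpha`, `reynolds`, `n_harmonics`, `period`,
#'   and (when both methods were run) the comparison percentages.
#' @export
glance.wss_fit <- function(x, ...) {
  out <- tibble(alpha = x$alpha, reynolds = x$reynolds,
                n_harmonics = x$n_harmonics,
                period = sp_period(x$spectrum))
  if (!is.null(x$comparison)) {
    out <- dplyr::bind_cols(out, x$comparison[
      c("pct_diff_median", "pct_diff_peak", "delta_osi")])
  }
  out
}

#' @rdname autoplot.wss_series
#' @export
autoplot.wss_fit <- function(object, ...) {
  ggplot2::ggplot(object$wss,
                  ggplot2::aes(x = .data$time, y = .data$wss,
                               colour = .data$method,
                               linetype = .data$method)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3,
                        colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "time (s)", y = "wall shear stress (Pa)",
                  colour = NULL, linetype = NULL,
                  title = sprintf("alpha = %.2f", object$alpha)) +
    ggplot2::theme_minimal()
}
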