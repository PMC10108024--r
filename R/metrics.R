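#' Oscillatory shear index
#'
#' `OSI = 0.5 * (1 - |int_0^T tau dt| / int_0^T |tau| dt)`, ranging from 0
#' for non-reversing wall shear stress to 0.5 for purely oscillatory
#' (zero-mean) shear.  Integrals are taken over exactly one period by the
#' trapezoid rule with periodic closure (the first sample is wrapped to
#' `t = T` when the grid covers `[0, T)`).  A degenerate all-zero signal
#' returns 0.
#'
#' @param s A `wss_series` (tibble with columns `time`, `wss`), or any
#'   data frame with those columns plus a known `period`.
#' @param period Cardiac period in s; taken from the series attribute when
#'   omitted.
#' @return The dimensionless OSI in `[0, 0.5]`.
#' @examples
#' t <- seq(0, 1, length.out = 256)[-256]
#' osi(tibble::tibble(time = t, wss = sin(2 * pi * t)), period = 1)
#' @export
osi <- function(s, period = NULL) {
  stopifnot(is.data.frame(s), all(c("time", "wss") %in% names(s)))
  period <- period %||% attr(s, "period", exact = TRUE)
  if (is.null(period)) {
    pw_input_error("`period` not given and not an attribute of the series")
  }
  denom <- periodic_int(s$time, abs(s$wss), period)
  if (denom == 0) return(0)
  num <- abs(periodic_int(s$time, s$wss, period))
  0.5 * (1 - num / denom)
}

#' Summarise a wall shear stress cycle
#'
#' Computes the summary quantities used to contrast reconstruction methods:
#' the extrema of `tau_w(t)` over the cycle, the cycle mean (trapezoid with
#' periodic closure, divided by the period), the median over time samples,
#' and the [osi()].  The median-over-time and the cycle mean are both
#' reported, as the two are used interchangeably as "time-averaged" WSS in
#' the literature.
#'
#' @inheritParams osi
#' @param method Method label for the output row; defaults to the series'
#'   `method` attribute.
#' @return A one-row tibble of class `hemo_summary` with columns `method`,
#'   `peak_wss`, `min_wss`, `time_avg_wss`, `time_median_wss`, `osi` (Pa
#'   where dimensional).
#' @export
wss_summary <- function(s, period = NULL, method = NULL) {
  stopifnot(is.data.frame(s), all(c("time", "wss") %in% names(s)))
  period <- period %||% attr(s, "period", exact = TRUE)
  if (is.null(period)) {
    pw_input_error("`period` not given and not an attribute of the series")
  }
  method <- method %||% attr(s, "method", exact = TRUE) %||% "unknown"
  # drop a duplicated cycle endpoint so sample statistics are unweighted
  keep <- rep(TRUE, nrow(s))
  n <- nrow(s)
  if (isTRUE(all.equal(s$time[n] - s$time[1], period, tolerance = 1e-8))) {
    keep[n] <- FALSE
  }
  tau <- s$wss[keep]
  out <- tibble(
    method = method,
    peak_wss = max(tau),
    min_wss = min(tau),
    time_avg_wss = periodic_int(s$time, s$wss, period) / period,
    time_median_wss = stats::median(tau),
    osi = osi(s, period))
  structure(out, class = c("hemo_summary", class(out)))
}

#' Compare Poiseuille and Womersley shear summaries
#'
#' Percent differences are expressed relative to the Womersley value, the
#' reference method.  Signs follow the clinically expected pattern:
#' `pct_diff_median` (and `pct_diff_mean`) is positive when the
#' quasi-steady Poiseuille estimate overestimates time-averaged WSS, and
#' `pct_diff_peak` is positive when Poiseuille underestimates the peak.
#' `delta_osi` is `womersley OSI - poiseuille OSI` (positive when the
#' quasi-steady method misses oscillatory shear).
#'
#' @param poiseuille,womersley One-row [wss_summary()] tibbles.
#' @return A one-row tibble with `pct_diff_median`, `pct_diff_mean`,
#'   `pct_diff_peak` (in %), `delta_osi`, and logical `undefined` flagging
#'   a zero Womersley reference quantity (affected fields are `NA`).
#' @export
compare_methods <- function(poiseuille, womersley) {
  stopifnot(inherits(poiseuille, "hemo_summary"),
            inherits(womersley, "hemo_summary"))
  p <- poiseuille
  w <- womersley
  pct <- function(num, ref) if (ref == 0) NA_real_ else 100 * num / ref
  out <- tibble(
    pct_diff_median = pct(p$time_median_wss - w$time_median_wss,
                          w$time_median_wss),
    pct_diff_mean = pct(p$time_avg_wss - w$time_avg_wss, w$time_avg_wss),
    pct_diff_peak = pct(w$peak_wss - p$peak_wss, w$peak_wss),
    delta_osi = w$osi - p$osi)
  out$undefined <- anyNA(out)
  if (out$undefined) {
    warn("a Womersley reference quantity is zero; percent difference undefined (NA)")
  }
  out
}
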