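#' Construct a one-dimensional velocity waveform
#'
#' A velocity waveform is one cardiac cycle of a 1D velocity signal, such as
#' the trace extracted from a pulsed-wave Doppler recording, stored as a
#' tibble with columns `time` (s) and `velocity` (m/s) plus attributes
#' `period` (s), `mode` and `label`.  `mode` states what the signal
#' physically is: the cross-sectional *mean* velocity or the *centerline*
#' (r = 0) velocity; downstream reconstructions treat the two differently.
#'
#' Sample times must be strictly increasing and lie within `[0, period)`
#' (they are shifted so the first sample is at 0).  At least 4 samples are
#' required; meaningful harmonic content needs many more.
#'
#' @param time Sample times in s.
#' @param velocity Velocities in m/s.
#' @param period Cardiac period in s.  If `NULL`, inferred as the sampled
#'   span plus the median sampling interval (i.e. samples covering `[0, T)`).
#' @param mode `"mean"` or `"centerline"`.
#' @param label Free-text label carried through to outputs.
#'
#' @return A tibble of class `vel_waveform`.
#' @examples
#' t <- seq(0, 1, length.out = 64)[-64]
#' waveform(t, 0.2 + 0.05 * cos(2 * pi * t))
#' @export
waveform <- function(time, velocity, period = NULL,
                     mode = c("mean", "centerline"), label = "") {
  mode <- match.arg(mode)
  time <- as.numeric(time)
  velocity <- as.numeric(velocity)
  if (length(time) != length(velocity)) {
    pw_input_error("`time` and `velocity` lengths differ")
  }
  if (length(time) < 4L) {
    pw_input_error(sprintf(
      "waveform needs at least 4 samples per period, got %d", length(time)))
  }
  if (anyNA(time) || anyNA(velocity) ||
      !all(is.finite(time)) || !all(is.finite(velocity))) {
    bad <- which(!is.finite(time) | !is.finite(velocity))[1]
    pw_input_error(sprintf("non-finite sample at row %d", bad))
  }
  d <- diff(time)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1] + 1L
    pw_input_error(sprintf(
      "sample times must be strictly increasing; row %d (t = %g) is not after row %d",
      bad, time[bad], bad - 1L))
  }
  time <- time - time[1]
  if (is.null(period)) {
    period <- (time[length(time)] - time[1]) + stats::median(d)
  }
  if (!is.finite(period) || period <= 0) {
    pw_input_error("`period` must be finite and positive")
  }
  if (time[length(time)] >= period) {
    pw_input_error(sprintf(
      "sample times span %g s but must lie within one period [0, %g)",
      time[length(time)], period))
  }
  out <- tibble(time = time, velocity = velocity)
  structure(out,
            class = c("vel_waveform", class(out)),
            period = period, mode = mode, label = label)
}

#' Coerce a data frame to a velocity waveform
#'
#' @param data A data frame whose first two columns (or columns named `time`
#'   and `velocity`) hold sample times and velocities.
#' @inheritParams waveform
#' @return A tibble of class `vel_waveform`.
#' @export
as_waveform <- function(data, period = NULL, mode = c("mean", "centerline"),
                        label = "") {
  stopifnot(is.data.frame(data))
  nms <- names(data)
  tcol <- if ("time" %in% nms) "time" else nms[1]
  vcol <- if ("velocity" %in% nms) "velocity" else nms[2]
  waveform(data[[tcol]], data[[vcol]], period = period,
           mode = match.arg(mode), label = label)
}

#' @export
print.vel_waveform <- function(x, ...) {
  cat(sprintf("<vel_waveform> %d samples, period %.4g s, mode '%s'%s\n",
              nrow(x), wf_period(x), wf_mode(x),
              if (nzchar(wf_label(x))) paste0(", '", wf_label(x), "'") else ""))
  NextMethod()
}

#' Waveform attributes
#'
#' Accessors for the period, mode and label attached to a [waveform()].
#' @param w A `vel_waveform`.
#' @return Period in s, mode string, or label string.
#' @export
wf_period <- function(w) attr(w, "period", exact = TRUE)

#' @rdname wf_period
#' @export
wf_mode <- function(w) attr(w, "mode", exact = TRUE)

#' @rdname wf_period
#' @export
wf_label <- function(w) attr(w, "label", exact = TRUE) %||% ""

#' Read a velocity waveform from a delimited text file
#'
#' Expects two columns (time, velocity), comma-, tab- or
#' whitespace-delimited, with an optional header line.  Clinical Doppler
#' exports commonly use cm/s and ms; the `units` and `time_units` flags
#' convert to SI at the boundary.
#'
#' @param path File path.
#' @param units Velocity units in the file, `"m/s"` or `"cm/s"`.
#' @param time_units Time units in the file, `"s"` or `"ms"`.
#' @inheritParams waveform
#' @return A tibble of class `vel_waveform` in SI units.
#' @export
read_waveform <- function(path, units = c("m/s", "cm/s"),
                          time_units = c("s", "ms"), period = NULL,
                          mode = c("mean", "centerline"), label = NULL) {
  units <- match.arg(units)
  time_units <- match.arg(time_units)
  mode <- match.arg(mode)
  if (!file.exists(path)) pw_input_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) pw_input_error(sprintf("empty file: %s", path))
  sep <- if (grepl(",", lines[1], fixed = TRUE)) "," else ""
  parse_row <- function(ln) {
    f <- if (nzchar(sep)) strsplit(ln, sep, fixed = TRUE)[[1]] else
      strsplit(ln, "[[:space:]]+")[[1]]
    suppressWarnings(as.numeric(trimws(f)))
  }
  first <- parse_row(lines[1])
  has_header <- anyNA(first) || length(first) < 2L
  body <- if (has_header) lines[-1] else lines
  if (length(body) < 4L) {
    pw_input_error(sprintf("%s: need at least 4 data rows, got %d",
                           path, length(body)))
  }
  rows <- lapply(body, parse_row)
  bad <- which(vapply(rows, function(r) length(r) < 2L || anyNA(r[1:2]),
                      logical(1)))
  if (length(bad) > 0L) {
    pw_input_error(sprintf("%s: malformed row %d: '%s'",
                           path, bad[1] + has_header, body[bad[1]]))
  }
  tt <- vapply(rows, `[`, numeric(1), 1L)
  vv <- vapply(rows, `[`, numeric(1), 2L)
  if (time_units == "ms") {
    tt <- tt / 1000
    if (!is.null(period)) period <- period  # period argument is always s
  }
  if (units == "cm/s") vv <- vv / 100
  withCallingHandlers(
    waveform(tt, vv, period = period, mode = mode,
             label = label %||% basename(path)),
    pw_input_error = function(e) {
      pw_input_error(sprintf("%s: %s", path, conditionMessage(e)))
    })
}

#' Write a waveform to CSV
#'
#' @param w A `vel_waveform`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(w, path) {
  utils::write.csv(as.data.frame(w)[c("time", "velocity")], path,
                   row.names = FALSE)
  invisible(path)
}

# remove linear cycle-to-cycle drift so the periodic extension is
# continuous.  The drift is the wrap discontinuity D = u(T) - u(0), with
# u(T) estimated by quadratic extrapolation through the last three
# samples; a linear ramp D/T is subtracted (mean-preserving).  Signals
# whose estimated discontinuity is below 0.1% of their range are treated
# as already periodic and left untouched, so well-resolved band-limited
# input passes through bit-identically.
detrend_periodic <- function(w) {
  t <- w$time
  u <- w$velocity
  n <- length(t)
  period <- wf_period(w)
  idx <- (n - 2):n
  fit <- stats::lm.fit(cbind(1, t[idx], t[idx]^2), u[idx])
  tT <- t[1] + period
  u_end <- sum(fit$coefficients * c(1, tT, tT^2))
  jump <- u_end - u[1]
  scale <- max(diff(range(u)), 1e-12)
  if (abs(jump) <= 1e-3 * scale) return(w)
  slope <- jump / period
  line <- slope * (t - t[1])
  u2 <- u - line + mean(line)
  waveform(t, u2, period = period, mode = wf_mode(w), label = wf_label(w))
}

#' Resample a waveform onto a uniform periodic grid
#'
#' Interpolates the waveform by a periodic cubic spline (the signal is
#' treated as exactly periodic with its stated period) and returns `n`
#' uniformly spaced samples on `[0, T)`, as required before discrete
#' Fourier analysis.  The time-mean is preserved to interpolation accuracy.
#'
#' @param w A `vel_waveform`.
#' @param n Number of output samples.
#' @param n_harmonics Optional target harmonic count; if given, `n` must
#'   satisfy the Nyquist constraint `n >= 2 * n_harmonics + 2`.
#' @return A uniformly sampled `vel_waveform`.
#' @export
resample_waveform <- function(w, n = 256L, n_harmonics = NULL) {
  stopifnot(inherits(w, "vel_waveform"))
  n <- as.integer(n)
  if (n < 4L) pw_input_error("`n` must be at least 4")
  if (!is.null(n_harmonics) && n < 2L * n_harmonics + 2L) {
    pw_input_error(sprintf(
      "n = %d violates the Nyquist constraint n >= 2N + 2 = %d for N = %d harmonics",
      n, 2L * n_harmonics + 2L, n_harmonics))
  }
  period <- wf_period(w)
  # replicate across the periodic boundary so cubic interpolation on the
  # central cycle is effectively periodic
  t3 <- c(w$time - period, w$time, w$time + period)
  u3 <- rep(w$velocity, 3L)
  f <- stats::splinefun(t3, u3, method = "fmm")
  tt <- seq(0, period, length.out = n + 1L)[seq_len(n)]
  waveform(tt, f(tt), period = period, mode = wf_mode(w), label = wf_label(w))
}
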