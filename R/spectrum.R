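#' Fourier decomposition of a velocity waveform
#'
#' Decomposes one cardiac cycle into complex harmonics
#' `U(t) = Re{ B0 + sum_{n=1}^{N} Bn exp(i n omega t) }` with
#' `omega = 2*pi/T`.  The one-sided convention is used: `B0` is the
#' time-mean and, for a uniformly sampled cycle of M points,
#' `Bn = (2/M) sum_k u_k exp(-i n omega t_k)`.  This is exactly the form the
#' pulsatile-flow equations consume, one shape factor per harmonic.
#'
#' Non-uniformly (or too coarsely) sampled waveforms are first resampled by
#' a periodic cubic spline onto `max(256, 4*(2N+2))` points.  The signal is
#' treated as exactly periodic: a linear detrend removes any cycle-to-cycle
#' drift, measured as the discontinuity of the periodic extension at the
#' cycle boundary (signals whose wrap discontinuity is below 0.1% of their
#' range are left untouched; `detrend = FALSE` disables the correction).
#'
#' @param w A [waveform()].
#' @param n_harmonics Number of harmonics N to retain (default 20).
#' @param detrend Remove linear drift across the cycle first?
#' @param resample `"auto"` resamples when needed; `"never"` errors if the
#'   sampling violates the Nyquist precondition `M >= 2N + 2` or is
#'   non-uniform.
#'
#' @return A tibble of class `fourier_spectrum` with columns `n` (0..N) and
#'   `b` (complex, m/s), and attributes `omega` (rad/s), `period`, `mode`,
#'   `label`.
#' @examples
#' w <- synth_cosine()
#' fourier_spectrum(w, n_harmonics = 5)
#' @export
fourier_spectrum <- function(w, n_harmonics = 20L, detrend = TRUE,
                             resample = c("auto", "never")) {
  stopifnot(inherits(w, "vel_waveform"))
  resample <- match.arg(resample)
  n_harmonics <- as.integer(n_harmonics)
  if (n_harmonics < 1L) pw_input_error("`n_harmonics` must be >= 1")
  m <- nrow(w)
  uniform <- is_uniform_grid(w$time) &&
    isTRUE(all.equal(m * (w$time[2] - w$time[1]), wf_period(w),
                     tolerance = 1e-6))
  need <- 2L * n_harmonics + 2L
  if (!uniform || m < need) {
    if (resample == "never") {
      pw_input_error(sprintf(paste0(
        "waveform must be uniformly sampled with M >= 2N + 2 = %d points ",
        "for N = %d harmonics (got M = %d%s)"), need, n_harmonics, m,
        if (uniform) "" else ", non-uniform"))
    }
    w <- resample_waveform(w, max(256L, 4L * need))
    m <- nrow(w)
  }
  if (detrend) w <- detrend_periodic(w)
  co <- stats::fft(w$velocity) / m
  b <- c(Re(co[1]), 2 * co[seq(2L, n_harmonics + 1L)])
  out <- tibble(n = 0:n_harmonics, b = as.complex(b))
  structure(out,
            class = c("fourier_spectrum", class(out)),
            omega = 2 * pi / wf_period(w),
            period = wf_period(w),
            mode = wf_mode(w),
            label = wf_label(w))
}

#' @export
print.fourier_spectrum <- function(x, ...) {
  cat(sprintf("<fourier_spectrum> N = %d harmonics, omega = %.4g rad/s, mode '%s'\n",
              max(x$n), sp_omega(x), sp_mode(x)))
  NextMethod()
}

#' Spectrum attributes
#'
#' Accessors for the fundamental angular frequency, period and mode of a
#' [fourier_spectrum()].
#' @param s A `fourier_spectrum`.
#' @return Numeric or string attribute value.
#' @export
sp_omega <- function(s) attr(s, "omega", exact = TRUE)

#' @rdname sp_omega
#' @export
sp_period <- function(s) attr(s, "period", exact = TRUE)

#' @rdname sp_omega
#' @export
sp_mode <- function(s) attr(s, "mode", exact = TRUE)

#' Build a spectrum directly from complex coefficients
#'
#' Constructs a [fourier_spectrum()] from a vector of one-sided complex
#' coefficients `c(B0, B1, ..., BN)` (the signal being
#' `Re{ B0 + sum Bn exp(i n omega t) }`).  Useful for analytic test
#' signals and for supplying pressure-gradient harmonics to
#' [pressure_profile()] or [fd_pulsatile()], in which case the
#' coefficients are in Pa/m rather than m/s.
#'
#' @param b Complex vector of coefficients, `b[1]` being the steady term.
#' @param period Fundamental period in s (or give `omega`).
#' @param omega Fundamental angular frequency in rad/s.
#' @param mode `"mean"` or `"centerline"`.
#' @param label Free-text label.
#' @return A `fourier_spectrum`.
#' @examples
#' as_spectrum(c(0.2, 0.05), period = 1)  # the default cosine test signal
#' @export
as_spectrum <- function(b, period = NULL, omega = NULL,
                        mode = c("mean", "centerline"), label = "") {
  mode <- match.arg(mode)
  if (is.null(omega)) {
    if (is.null(period)) pw_input_error("supply `period` or `omega`")
    omega <- 2 * pi / period
  }
  if (!is.finite(omega) || omega <= 0) {
    pw_input_error("fundamental frequency must be finite and positive")
  }
  if (length(b) < 1 || abs(Im(as.complex(b)[1])) > 1e-12 * max(Mod(b), 1)) {
    pw_input_error("`b` must start with a (real) steady coefficient B0")
  }
  new_spectrum(seq_along(b) - 1L, as.complex(b), omega, mode, label)
}

# internal constructor used by rescaling operations
new_spectrum <- function(n, b, omega, mode, label = "") {
  out <- tibble(n = n, b = as.complex(b))
  structure(out,
            class = c("fourier_spectrum", class(out)),
            omega = omega, period = 2 * pi / omega, mode = mode,
            label = label)
}

#' Reconstruct the 1D signal from its spectrum
#'
#' Evaluates `Re{ B0 + sum Bn exp(i n omega t) }` on an arbitrary time
#' grid.  Decomposing a band-limited waveform and reconstructing at its
#' original sample times reproduces the input to floating-point accuracy.
#'
#' @param s A [fourier_spectrum()].
#' @param time Time grid in s; defaults to 200 points covering one period.
#' @return A tibble with columns `time` and `velocity`.
#' @export
reconstruct_waveform <- function(s, time = NULL) {
  stopifnot(inherits(s, "fourier_spectrum"))
  time <- time %||% default_time_grid(sp_period(s))
  tibble(time = time, velocity = eval_spectrum(s, time))
}

# Re{ B0 + sum Bn e^(i n w t) } as a bare numeric vector
eval_spectrum <- function(s, time) {
  omega <- sp_omega(s)
  acc <- rep(Re(s$b[s$n == 0]), length(time))
  for (k in which(s$n > 0)) {
    acc <- acc + Re(s$b[k] * exp(1i * s$n[k] * omega * time))
  }
  acc
}

#' Tidy a Fourier spectrum
#'
#' @param x A `fourier_spectrum`.
#' @param ... Unused.
#' @return A tibble with one row per harmonic: `n`, `re`, `im`, `modulus`,
#'   `phase` (rad) and `frequency` (Hz).
#' @export
tidy.fourier_spectrum <- function(x, ...) {
  tibble(n = x$n,
         re = Re(x$b), im = Im(x$b),
         modulus = Mod(x$b), phase = Arg(x$b),
         frequency = x$n * sp_omega(x) / (2 * pi))
}

#' Write a spectrum to CSV (columns n, re, im)
#'
#' @param s A `fourier_spectrum`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(s, path) {
  utils::write.csv(data.frame(n = s$n, re = Re(s$b), im = Im(s$b)),
                   path, row.names = FALSE)
  invisible(path)
}
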