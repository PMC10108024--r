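#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_wider
NULL

# condition helpers: input errors (bad files/arguments) vs numerical failures
pw_input_error <- function(msg, ...) {
  abort(msg, class = "pw_input_error", ...)
}
pw_numeric_error <- function(msg, ...) {
  abort(msg, class = "pw_numeric_error", ...)
}

# composite trapezoid on possibly non-uniform x
trapz_int <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# composite Simpson on a uniform grid; falls back to trapezoid when the
# point count is even or the grid is non-uniform
simpson_int <- function(x, y) {
  n <- length(x)
  h <- diff(x)
  if (n < 3 || n %% 2 == 0 || diff(range(h)) > 1e-10 * mean(h)) {
    return(trapz_int(x, y))
  }
  h <- h[1]
  i <- seq(2, n - 1)
  h / 3 * (y[1] + y[n] + sum(y[i] * ifelse(i %% 2 == 0, 4, 2)))
}

# integral of one full period of a sampled periodic signal; samples on
# [0, T) are closed by wrapping the first value to t = T
periodic_int <- function(t, y, period) {
  n <- length(t)
  if (isTRUE(all.equal(t[n] - t[1], period, tolerance = 1e-8))) {
    return(trapz_int(t, y))
  }
  trapz_int(c(t, t[1] + period), c(y, y[1]))
}

is_uniform_grid <- function(x, tol = 1e-8) {
  d <- diff(x)
  length(d) > 0 && diff(range(d)) <= tol * mean(d)
}

# default time grid: m points covering [0, T)
default_time_grid <- function(period, m = 200L) {
  seq(0, period, length.out = m + 1L)[seq_len(m)]
}
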