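#' Finite-difference solution of unsteady axisymmetric pipe flow
#'
#' Independent numerical ground truth for the analytic solutions: marches
#' the unsteady axisymmetric momentum balance
#' `rho du/dt = G(t) + mu (1/r) d/dr (r du/dr)` with no-slip at `r = R` and
#' symmetry at the axis, driven by the pressure-gradient harmonics
#' `G(t) = -dp/dx`.  Crank-Nicolson time stepping (unconditionally stable,
#' second-order) on a uniform radial grid; the march starts from the steady
#' Poiseuille profile of the mean gradient and continues until two
#' successive cycles differ by less than `tol` in relative L2 norm.
#'
#' @param pgrad A [fourier_spectrum()] of `-dp/dx` harmonics (Pa/m).
#' @param vessel A [vessel_spec()].
#' @param n_r Number of radial points (including axis and wall).
#' @param n_t Time steps per cycle.
#' @param n_cycles Maximum cycles to march (>= 3).
#' @param tol Relative cycle-to-cycle L2 convergence tolerance.
#' @return A `flow_profile` (method `"fd"`) holding the final, periodic
#'   cycle on the native `n_r` x `n_t` grid.
#' @export
fd_pulsatile <- function(pgrad, vessel, n_r = 129L, n_t = 400L,
                         n_cycles = 60L, tol = 1e-6) {
  stopifnot(inherits(pgrad, "fourier_spectrum"))
  n_r <- as.integer(n_r)
  n_t <- as.integer(n_t)
  if (n_cycles < 3L) pw_input_error("`n_cycles` must be >= 3")
  R <- vessel$radius
  mu <- vessel$viscosity
  rho <- vessel$density
  period <- sp_period(pgrad)
  h <- R / (n_r - 1L)
  dt <- period / n_t
  r <- seq(0, R, length.out = n_r)
  ni <- n_r - 1L                     # unknowns j = 0 .. n_r-2 (wall fixed 0)
  # spatial operator L u = u'' + u'/r (axis: 4(u1 - u0)/h^2 by symmetry)
  L <- matrix(0, ni, ni)
  L[1, 1] <- -4 / h^2
  L[1, 2] <- 4 / h^2
  for (j in 2:ni) {
    rj <- r[j]
    L[j, j - 1] <- 1 / h^2 - 1 / (2 * rj * h)
    L[j, j] <- -2 / h^2
    if (j < ni) L[j, j + 1] <- 1 / h^2 + 1 / (2 * rj * h)
  }
  nu <- mu / rho
  A <- diag(ni) - (nu * dt / 2) * L
  B <- diag(ni) + (nu * dt / 2) * L
  Ainv <- solve(A)
  M <- Ainv %*% B
  g_of_t <- function(t) eval_spectrum(pgrad, t)
  # start from the steady profile of the mean gradient
  g0 <- Re(pgrad$b[pgrad$n == 0])
  u <- g0 * R^2 / (4 * mu) * (1 - (r[seq_len(ni)] / R)^2)
  t_grid <- seq(0, period, length.out = n_t + 1L)[seq_len(n_t)]
  prev_cycle <- NULL
  converged <- FALSE
  resid <- Inf
  for (cyc in seq_len(n_cycles)) {
    snap <- matrix(0, n_r, n_t)
    for (m in seq_len(n_t)) {
      snap[, m] <- c(u, 0)
      tm <- t_grid[m]
      gbar <- (g_of_t(tm) + g_of_t(tm + dt)) / 2
      u <- as.vector(M %*% u) + as.vector(Ainv %*% rep(dt * gbar / rho, ni))
    }
    if (!is.null(prev_cycle)) {
      num <- sqrt(sum((snap - prev_cycle)^2))
      den <- sqrt(sum(prev_cycle^2))
      resid <- if (den == 0) 0 else num / den
      if (resid < tol) {
        prev_cycle <- snap
        converged <- TRUE
        break
      }
    }
    prev_cycle <- snap
  }
  if (!converged) {
    pw_numeric_error(sprintf(
      "finite-difference march did not reach periodicity in %d cycles (residual %.3g)",
      n_cycles, resid))
  }
  new_profile(t_grid, r, prev_cycle, radius = R, period = period,
              method = "fd")
}

#' Numerical flow rate of a velocity profile
#'
#' `Q(t) = 2 pi int_0^R U(r, t) r dr` by composite Simpson (trapezoid on
#' non-Simpson grids) at every time sample; used to cross-check the
#' analytic flow-rate formulas.
#'
#' @param p A `flow_profile` whose radial grid includes 0 and R.
#' @return A tibble of class `flow_series` with columns `time`, `flow`.
#' @export
numeric_flow <- function(p) {
  stopifnot(inherits(p, "flow_profile"))
  r <- attr(p, "r_grid")
  t <- attr(p, "t_grid")
  U <- profile_matrix(p)
  flow <- vapply(seq_along(t), function(m) {
    2 * pi * simpson_int(r, U[, m] * r)
  }, numeric(1))
  out <- tibble(time = t, flow = flow)
  structure(out, class = c("flow_series", class(out)),
            period = profile_period(p), method = profile_method(p))
}

#' Numerical wall shear stress of a velocity profile
#'
#' One-sided second-order finite difference of the velocity at the wall,
#' `du/dr|_R = (3 u_J - 4 u_{J-1} + u_{J-2}) / (2h)`, multiplied by the
#' viscosity and sign-flipped to the antegrade-positive convention.  Used
#' to cross-check the analytic shear formulas.
#'
#' @param p A `flow_profile` on a uniform radial grid reaching `r = R`.
#' @param vessel A [vessel_spec()].
#' @return A tibble of class `wss_series`.
#' @export
numeric_wss <- function(p, vessel) {
  stopifnot(inherits(p, "flow_profile"))
  r <- attr(p, "r_grid")
  if (!is_uniform_grid(r)) {
    pw_input_error("numeric_wss requires a uniform radial grid")
  }
  n <- length(r)
  if (n < 101L) {
    warn(sprintf(paste0(
      "radial grid has only %d points; wall-derivative truncation error ",
      "is O(h^2) ~ %.1e relative"), n, (1 / (n - 1))^2 * 10))
  }
  h <- r[2] - r[1]
  U <- profile_matrix(p)
  dudr <- (3 * U[n, ] - 4 * U[n - 1, ] + U[n - 2, ]) / (2 * h)
  new_wss_series(attr(p, "t_grid"), -vessel$viscosity * dudr,
                 period = profile_period(p), method = profile_method(p))
}

#' Area-mean velocity waveform of a profile
#'
#' The cross-sectional average `U_1D(t) = Q(t) / (pi R^2)` computed by
#' quadrature, returned as a [waveform()] in mean mode so it can be fed
#' back into the velocity-driven reconstruction.
#'
#' @inheritParams numeric_flow
#' @return A `vel_waveform`.
#' @export
area_mean_waveform <- function(p) {
  q <- numeric_flow(p)
  waveform(q$time, q$flow / (pi * profile_radius(p)^2),
           period = profile_period(p), mode = "mean",
           label = paste0("area-mean of ", profile_method(p)))
}
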