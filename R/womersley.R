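#' Per-harmonic Womersley factors
#'
#' For harmonic n the pulsatile pipe-flow solution is governed by the
#' complex parameter `Lambda_n = alpha * sqrt(n) * i^(3/2)` with the branch
#' `i^(3/2) = exp(i 3 pi / 4)` (positive imaginary part), where `alpha` is
#' the Womersley number at the fundamental frequency.  This returns the
#' cached factors entering the velocity, flow and shear formulas:
#'
#' * `shape_denominator`: `1 - 2 J1(L)/(L J0(L))`, which is also the ratio
#'   of cross-sectional mean to driving amplitude;
#' * `wall_gradient_factor`: `-L J1(L) / (R J0(L))`, the wall velocity
#'   gradient per unit harmonic amplitude, signed so that multiplying by
#'   the viscosity yields wall shear stress positive in the antegrade
#'   (mean-flow) direction;
#' * `centerline_factor`: `1 - 1/J0(L)`, the centerline value of the
#'   radial shape function.
#'
#' @param vessel A [vessel_spec()].
#' @param omega Fundamental angular frequency in rad/s.
#' @param n Harmonic indices (>= 1), vectorised.
#'
#' @return A tibble with complex columns `lambda`, `shape_denominator`,
#'   `wall_gradient_factor`, `centerline_factor` and numeric `n`, `alpha_n`.
#' @export
harmonic_factors <- function(vessel, omega, n) {
  stopifnot(inherits(vessel, "vessel_spec"))
  if (any(n < 1)) pw_input_error("harmonic index `n` must be >= 1")
  alpha <- womersley_number(vessel, omega = omega)
  i32 <- exp(1i * 3 * pi / 4)
  rows <- lapply(n, function(nn) {
    lam <- alpha * sqrt(nn) * i32
    r10 <- besselj1_over_j0(lam)
    denom <- 1 - 2 * r10 / lam
    if (!is.finite(Re(denom)) || Mod(denom) < 1e-300) {
      pw_numeric_error(sprintf(
        "degenerate harmonic factor at n = %d (alpha = %.3g)", nn, alpha))
    }
    # centerline shape 1 - 1/J0(L): J0 grows like e^|Im L|, so 1/J0 may
    # underflow harmlessly for large arguments
    inv_j0 <- if (abs(Im(lam)) <= .bessel_im_max) {
      j0 <- besselj01(lam)$j0
      if (Mod(j0) < 1e-300) {
        pw_numeric_error(sprintf(
          "J0(Lambda) vanishes to double precision at n = %d (alpha = %.3g)",
          nn, alpha))
      }
      1 / j0
    } else {
      0 + 0i
    }
    tibble(n = nn,
           alpha_n = alpha * sqrt(nn),
           lambda = lam,
           shape_denominator = denom,
           wall_gradient_factor = -lam * r10 / vessel$radius,
           centerline_factor = 1 - inv_j0)
  })
  dplyr::bind_rows(rows)
}

# coerce waveform-or-spectrum input, converting centerline mode to mean
resolve_spectrum <- function(w, vessel, n_harmonics) {
  s <- if (inherits(w, "fourier_spectrum")) w else
    fourier_spectrum(w, n_harmonics = n_harmonics)
  if (sp_mode(s) == "centerline") s <- centerline_to_mean(s, vessel)
  s
}

#' Convert a centerline-velocity spectrum to mean-velocity form
#'
#' The pulsatile-flow formulas are written in terms of the cross-sectional
#' mean velocity, but Doppler recordings often track the centerline
#' (r = 0) velocity.  For the steady component the parabolic profile gives
#' mean = centerline / 2; each harmonic is divided by its centerline shape
#' value `(1 - 1/J0(Ln)) / (1 - 2 J1(Ln)/(Ln J0(Ln)))`, so that the
#' reconstructed centerline velocity of the resulting profile reproduces
#' the measured waveform.  As `alpha -> 0` every factor tends to the
#' parabolic value 2.
#'
#' @param s A [fourier_spectrum()] with mode `"centerline"`.
#' @param vessel A [vessel_spec()].
#' @return A `fourier_spectrum` with mode `"mean"`.
#' @export
centerline_to_mean <- function(s, vessel) {
  stopifnot(inherits(s, "fourier_spectrum"))
  if (sp_mode(s) != "centerline") {
    pw_input_error("spectrum mode is not 'centerline'")
  }
  hf <- harmonic_factors(vessel, sp_omega(s), s$n[s$n > 0])
  factor <- hf$centerline_factor / hf$shape_denominator
  if (any(Mod(factor) < 1e-12)) {
    pw_numeric_error("degenerate centerline shape value; cannot rescale")
  }
  b <- s$b
  b[s$n == 0] <- b[s$n == 0] / 2
  b[s$n > 0] <- b[s$n > 0] / factor
  new_spectrum(s$n, b, sp_omega(s), mode = "mean", label = sp_label(s))
}

sp_label <- function(s) attr(s, "label", exact = TRUE) %||% ""

#' Womersley radial velocity profile
#'
#' Reconstructs the full time-varying radial velocity profile `U(r, t)`
#' driven by a 1D mean-velocity waveform: a steady parabolic component
#' `2 B0 (1 - (r/R)^2)` plus, for each harmonic, the classical Womersley
#' radial shape `(1 - J0(Ln r/R)/J0(Ln)) / (1 - 2 J1(Ln)/(Ln J0(Ln)))`
#' scaled by the harmonic amplitude `Bn`.  The construction guarantees
#' no-slip at the wall and that the cross-sectional area-mean at every
#' instant reproduces the driving waveform.
#'
#' @param w A [waveform()] or [fourier_spectrum()]; centerline-mode input
#'   is converted via [centerline_to_mean()].
#' @param vessel A [vessel_spec()].
#' @param r Radial grid in m within `[0, R]`; defaults to 101 uniform
#'   points including both endpoints.
#' @param time Time grid in s; defaults to 200 points covering one period.
#' @param n_harmonics Harmonic count when `w` is a waveform.
#'
#' @return A tibble of class `flow_profile` with columns `time`, `r`,
#'   `velocity`, ordered by time then radius, and attributes `radius`,
#'   `period`, `method`.
#' @examples
#' p <- womersley_profile(synth_cosine(), vessel_spec(diameter = 4e-3))
#' @export
womersley_profile <- function(w, vessel, r = NULL, time = NULL,
                              n_harmonics = 20L) {
  s <- resolve_spectrum(w, vessel, n_harmonics)
  R <- vessel$radius
  r <- r %||% seq(0, R, length.out = 101L)
  if (any(r < 0) || any(r > R * (1 + 1e-12))) {
    pw_input_error("radial grid must lie within [0, R]")
  }
  time <- time %||% default_time_grid(sp_period(s))
  omega <- sp_omega(s)
  rr <- r / R
  b0 <- Re(s$b[s$n == 0])
  U <- outer(2 * b0 * (1 - rr^2), rep(1, length(time)))
  ns <- s$n[s$n > 0]
  if (length(ns) > 0) {
    hf <- harmonic_factors(vessel, omega, ns)
    for (k in seq_along(ns)) {
      bn <- s$b[s$n == ns[k]]
      if (bn == 0) next
      shape <- (1 - besselj0_ratio(hf$lambda[k], rr)) / hf$shape_denominator[k]
      U <- U + Re(outer(shape, bn * exp(1i * ns[k] * omega * time)))
    }
  }
  new_profile(time, r, U, radius = R, period = sp_period(s),
              method = "womersley")
}

# build the long-form profile tibble from a (r x t) matrix
new_profile <- function(time, r, U, radius, period, method) {
  tt <- rep(time, each = length(r))
  rr <- rep(r, times = length(time))
  out <- tibble(time = tt, r = rr, velocity = as.vector(U))
  structure(out,
            class = c("flow_profile", class(out)),
            radius = radius, period = period, method = method,
            r_grid = r, t_grid = time)
}

#' @export
print.flow_profile <- function(x, ...) {
  cat(sprintf("<flow_profile> method '%s', %d radii x %d times, R = %.3g mm\n",
              profile_method(x), length(attr(x, "r_grid")),
              length(attr(x, "t_grid")), attr(x, "radius") * 1e3))
  NextMethod()
}

#' Profile attributes
#'
#' Accessors for the grids and metadata of a `flow_profile`.
#' @param p A `flow_profile`.
#' @return Numeric vector or string.
#' @export
profile_method <- function(p) attr(p, "method", exact = TRUE)

#' @rdname profile_method
#' @export
profile_radius <- function(p) attr(p, "radius", exact = TRUE)

#' @rdname profile_method
#' @export
profile_period <- function(p) attr(p, "period", exact = TRUE)

# (r x t) velocity matrix view of a long profile tibble
profile_matrix <- function(p) {
  r <- attr(p, "r_grid")
  t <- attr(p, "t_grid")
  matrix(p$velocity, nrow = length(r), ncol = length(t))
}

#' Volumetric flow rate of the Womersley reconstruction
#'
#' Integrating the Womersley profile over the cross-section collapses to
#' `Q(t) = pi R^2 * U_1D(t)`: each harmonic's radial shape function has
#' unit area-mean by construction, so the flow rate is the vessel area
#' times the driving mean-velocity waveform.
#'
#' @inheritParams womersley_profile
#' @return A tibble of class `flow_series` with columns `time`, `flow`
#'   (m^3/s).
#' @export
womersley_flow <- function(w, vessel, time = NULL, n_harmonics = 20L) {
  s <- resolve_spectrum(w, vessel, n_harmonics)
  time <- time %||% default_time_grid(sp_period(s))
  out <- tibble(time = time,
                flow = pi * vessel$radius^2 * eval_spectrum(s, time))
  structure(out, class = c("flow_series", class(out)),
            period = sp_period(s), method = "womersley")
}

#' Womersley wall shear stress
#'
#' Wall shear stress over the cardiac cycle from the velocity-driven
#' Womersley solution: the steady Poiseuille part `4 mu B0 / R` plus the
#' per-harmonic unsteady part
#' `Re{ mu Bn [-Ln J1(Ln)/(R J0(Ln))] / [1 - 2 J1(Ln)/(Ln J0(Ln))] e^(i n w t) }`.
#' The sign convention is antegrade-positive: steady forward flow gives
#' `+4 mu U / R`, and retrograde (proximally directed) shear is negative.
#' In the `alpha -> 0` limit the result reduces to the quasi-steady
#' Poiseuille value `4 mu U_1D(t) / R`.
#'
#' @inheritParams womersley_profile
#' @return A tibble of class `wss_series` with columns `time`, `wss` (Pa)
#'   and attributes `period`, `method`, `sign_convention`.
#' @examples
#' womersley_wss(synth_cosine(), vessel_spec(diameter = 4e-3))
#' @export
womersley_wss <- function(w, vessel, time = NULL, n_harmonics = 20L) {
  s <- resolve_spectrum(w, vessel, n_harmonics)
  time <- time %||% default_time_grid(sp_period(s))
  omega <- sp_omega(s)
  mu <- vessel$viscosity
  tau <- rep(4 * mu * Re(s$b[s$n == 0]) / vessel$radius, length(time))
  ns <- s$n[s$n > 0]
  if (length(ns) > 0) {
    hf <- harmonic_factors(vessel, omega, ns)
    for (k in seq_along(ns)) {
      bn <- s$b[s$n == ns[k]]
      coef <- mu * bn * hf$wall_gradient_factor[k] / hf$shape_denominator[k]
      tau <- tau + Re(coef * exp(1i * ns[k] * omega * time))
    }
  }
  new_wss_series(time, tau, period = sp_period(s), method = "womersley")
}

new_wss_series <- function(time, wss, period, method) {
  out <- tibble(time = time, wss = wss)
  structure(out, class = c("wss_series", class(out)),
            period = period, method = method,
            sign_convention = "antegrade-positive")
}

#' @export
print.wss_series <- function(x, ...) {
  cat(sprintf("<wss_series> method '%s', %d samples over %.4g s (antegrade-positive)\n",
              attr(x, "method"), nrow(x), attr(x, "period")))
  NextMethod()
}

#' Pressure-driven Womersley profile
#'
#' The classical Womersley solution driven by the harmonics of the axial
#' pressure gradient `G(t) = -dp/dx` rather than by a measured velocity:
#' steady component `G0 R^2 / (4 mu) * (1 - (r/R)^2)` plus per-harmonic
#' `Re{ -i Gn/(rho n omega) (1 - J0(Ln r/R)/J0(Ln)) e^(i n omega t) }`.
#' Used as a comparator for the velocity-driven method and as the analytic
#' reference for the finite-difference oracle.
#'
#' @param pgrad A [fourier_spectrum()] whose coefficients are harmonics of
#'   `-dp/dx` in Pa/m (the `b` column; mode is ignored).
#' @inheritParams womersley_profile
#' @return A tibble of class `flow_profile`, method `"pressure_driven"`.
#' @export
pressure_profile <- function(pgrad, vessel, r = NULL, time = NULL) {
  stopifnot(inherits(pgrad, "fourier_spectrum"))
  R <- vessel$radius
  r <- r %||% seq(0, R, length.out = 101L)
  if (any(r < 0) || any(r > R * (1 + 1e-12))) {
    pw_input_error("radial grid must lie within [0, R]")
  }
  time <- time %||% default_time_grid(sp_period(pgrad))
  omega <- sp_omega(pgrad)
  rr <- r / R
  g0 <- Re(pgrad$b[pgrad$n == 0])
  U <- outer(g0 * R^2 / (4 * vessel$viscosity) * (1 - rr^2),
             rep(1, length(time)))
  ns <- pgrad$n[pgrad$n > 0]
  if (length(ns) > 0) {
    hf <- harmonic_factors(vessel, omega, ns)
    for (k in seq_along(ns)) {
      gn <- pgrad$b[pgrad$n == ns[k]]
      if (gn == 0) next
      cn <- -1i * gn / (vessel$density * ns[k] * omega)
      shape <- 1 - besselj0_ratio(hf$lambda[k], rr)
      U <- U + Re(outer(cn * shape, exp(1i * ns[k] * omega * time)))
    }
  }
  new_profile(time, r, U, radius = R, period = sp_period(pgrad),
              method = "pressure_driven")
}
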