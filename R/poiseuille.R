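#' Quasi-steady Poiseuille velocity profile
#'
#' The clinical-comparator reconstruction: at every instant the profile is
#' assumed parabolic, `U(r, t) = 2 U_1D(t) (1 - (r/R)^2)`, ignoring all
#' frequency content of the waveform.  The instantaneous mean velocity is
#' evaluated from the same band-limited Fourier representation used by the
#' Womersley reconstruction so the two methods see identical input.
#' Centerline-mode input is halved (parabolic centerline = 2 x mean).
#'
#' @inheritParams womersley_profile
#' @return A tibble of class `flow_profile`, method `"poiseuille"`.
#' @examples
#' poiseuille_profile(synth_cosine(), vessel_spec(diameter = 4e-3))
#' @export
poiseuille_profile <- function(w, vessel, r = NULL, time = NULL,
                               n_harmonics = 20L) {
  s <- resolve_spectrum_qs(w, vessel, n_harmonics)
  R <- vessel$radius
  r <- r %||% seq(0, R, length.out = 101L)
  if (any(r < 0) || any(r > R * (1 + 1e-12))) {
    pw_input_error("radial grid must lie within [0, R]")
  }
  time <- time %||% default_time_grid(sp_period(s))
  u1d <- eval_spectrum(s, time)
  rr <- r / R
  U <- outer(2 * (1 - rr^2), u1d)
  new_profile(time, r, U, radius = R, period = sp_period(s),
              method = "poiseuille")
}

# quasi-steady mode handling: a centerline waveform maps to mean velocity
# by the parabolic factor 2 at every instant
resolve_spectrum_qs <- function(w, vessel, n_harmonics) {
  s <- if (inherits(w, "fourier_spectrum")) w else
    fourier_spectrum(w, n_harmonics = n_harmonics)
  if (sp_mode(s) == "centerline") {
    s <- new_spectrum(s$n, s$b / 2, sp_omega(s), mode = "mean",
                      label = sp_label(s))
  }
  s
}

#' Quasi-steady Poiseuille wall shear stress
#'
#' `tau_w(t) = 4 mu U_1D(t) / R`, the instantaneous version of the steady
#' parabolic-flow formula commonly employed in flow-mediated dilation
#' studies.  Antegrade-positive: the sign of the shear follows the sign of
#' the instantaneous mean velocity, so this estimate can only reverse when
#' the measured velocity itself reverses.
#'
#' @inheritParams womersley_profile
#' @return A tibble of class `wss_series`, method `"poiseuille"`.
#' @export
poiseuille_wss <- function(w, vessel, time = NULL, n_harmonics = 20L) {
  s <- resolve_spectrum_qs(w, vessel, n_harmonics)
  time <- time %||% default_time_grid(sp_period(s))
  tau <- 4 * vessel$viscosity * eval_spectrum(s, time) / vessel$radius
  new_wss_series(time, tau, period = sp_period(s), method = "poiseuille")
}

#' Quasi-steady Poiseuille flow rate
#'
#' `Q(t) = pi R^2 U_1D(t)`; identical in algebraic form to the Womersley
#' flow rate, since both equal vessel area times mean velocity.
#'
#' @inheritParams womersley_profile
#' @return A tibble of class `flow_series`, method `"poiseuille"`.
#' @export
poiseuille_flow <- function(w, vessel, time = NULL, n_harmonics = 20L) {
  s <- resolve_spectrum_qs(w, vessel, n_harmonics)
  time <- time %||% default_time_grid(sp_period(s))
  out <- tibble(time = time,
                flow = pi * vessel$radius^2 * eval_spectrum(s, time))
  structure(out, class = c("flow_series", class(out)),
            period = sp_period(s), method = "poiseuille")
}
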