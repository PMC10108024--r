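#' Vessel and fluid specification
#'
#' Bundles the geometric and rheological constants of a straight arterial
#' segment: the time-averaged lumen radius, the dynamic viscosity and the
#' density of blood.  Clinical measurements are usually reported as a
#' diameter, so either `diameter` or `radius` may be given (in metres).
#' Defaults model blood as an incompressible Newtonian fluid with
#' density 1060 kg/m^3 and viscosity 4.5 mPa s.
#'
#' @param diameter Time-averaged lumen diameter in m.
#' @param radius Time-averaged lumen radius in m (alternative to `diameter`).
#' @param viscosity Dynamic viscosity in Pa s.
#' @param density Density in kg/m^3.
#'
#' @return An object of class `vessel_spec`: a list with elements `radius`,
#'   `viscosity`, `density`.
#' @examples
#' vessel_spec(diameter = 4e-3)
#' @export
vessel_spec <- function(diameter = NULL, radius = NULL,
                        viscosity = 4.5e-3, density = 1060) {
  if (is.null(radius)) {
    if (is.null(diameter)) {
      pw_input_error("supply either `diameter` or `radius`")
    }
    radius <- diameter / 2
  } else if (!is.null(diameter)) {
    pw_input_error("supply only one of `diameter` and `radius`")
  }
  vals <- c(radius = radius, viscosity = viscosity, density = density)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    pw_input_error("radius, viscosity and density must be finite and positive")
  }
  structure(list(radius = radius, viscosity = viscosity, density = density),
            class = "vessel_spec")
}

#' @export
print.vessel_spec <- function(x, ...) {
  cat(sprintf(
    "<vessel_spec> radius %.3g mm, viscosity %.3g mPa s, density %.4g kg/m^3\n",
    x$radius * 1e3, x$viscosity * 1e3, x$density))
  invisible(x)
}

#' Womersley number
#'
#' The dimensionless ratio of transient inertial to viscous forces,
#' `alpha = R * sqrt(n * omega * rho / mu)`, which controls the shape of the
#' pulsatile velocity profile: near 1 the profile is quasi-parabolic, large
#' values give blunted, phase-lagged profiles.
#'
#' @param vessel A [vessel_spec()].
#' @param period Cardiac period in s (fundamental `omega = 2*pi/period`).
#' @param omega Fundamental angular frequency in rad/s (alternative to
#'   `period`).
#' @param n Harmonic index; `n = 1` gives the conventional Womersley number.
#'
#' @return Dimensionless Womersley number (vectorised over `n`).
#' @examples
#' womersley_number(vessel_spec(radius = 2e-3), period = 60 / 70)
#' @export
womersley_number <- function(vessel, period = NULL, omega = NULL, n = 1) {
  stopifnot(inherits(vessel, "vessel_spec"))
  if (is.null(omega)) {
    if (is.null(period)) pw_input_error("supply `period` or `omega`")
    omega <- 2 * pi / period
  }
  if (!is.finite(omega) || omega < 0) {
    pw_input_error("`omega` must be finite and non-negative")
  }
  vessel$radius * sqrt(n * omega * vessel$density / vessel$viscosity)
}

# advisory Reynolds number based on diameter and mean velocity
reynolds_number <- function(vessel, mean_velocity) {
  2 * vessel$radius * abs(mean_velocity) * vessel$density / vessel$viscosity
}
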