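# Built-in physiologic waveform templates.
#
# Each template is a fixed table of relative harmonic amplitudes and phases
# (amplitude relative to the cycle mean) chosen to resemble the classic
# Doppler appearance of the artery: a monophasic common-carotid-like wave
# (sharp systolic peak, dicrotic wave, velocity antegrade throughout) and
# triphasic brachial-/femoral-like waves (systolic peak, early-diastolic
# reverse phase, small secondary forward wave).  They are synthetic
# stand-ins for reduced-order-model output, not fits to any measured
# recording.  Vessel radii are set so the rest-state (70 beats/min)
# Womersley numbers are 4.3 / 4.2 / 4.8, and per-state mean velocities
# follow the rest/fear/exercise Reynolds numbers of a young-adult systemic
# circulation model (fear 100 beats/min, exercise 150 beats/min).
.pw_templates <- list(
  carotid_like = list(
    alpha_rest = 4.3,
    reynolds = c(rest = 797, fear = 769, exercise = 1150),
    amp = c(0.559396, 0.355174, 0.374729, 0.312028, 0.203707, 0.127762,
            0.0769065, 0.0423631, 0.0214504, 0.0100348, 0.00433488,
            0.00172866),
    phase = c(-1.30049, -2.05002, -2.85972, 2.28148, 1.21992, 0.245682,
              -0.749521, -1.75864, -2.76486, 2.51324, 1.50797, 0.502656),
    class = "monophasic"),
  brachial_like = list(
    alpha_rest = 4.2,
    reynolds = c(rest = 708, fear = 677, exercise = 1044),
    amp = c(0.355855, 0.506832, 0.600882, 0.464287, 0.256131, 0.128028,
            0.0706638, 0.0389241, 0.0213774, 0.010948, 0.00485197,
            0.00189695),
    phase = c(-0.623161, -1.31133, -2.52697, 2.44044, 1.27486, 0.387253,
              -0.412355, -1.23878, -2.10176, -3.06176, 2.22052, 1.24288),
    class = "triphasic"),
  femoral_like = list(
    alpha_rest = 4.8,
    reynolds = c(rest = 1393, fear = 1475, exercise = 3141),
    amp = c(0.516315, 0.738004, 0.754459, 0.468318, 0.222724, 0.119741,
            0.0653949, 0.0329217, 0.014855, 0.00582005, 0.00203608,
            0.00065047),
    phase = c(-0.618851, -1.4013, -2.69512, 2.30666, 1.34065, 0.568228,
              -0.294461, -1.20578, -2.16907, 3.14159, 2.19176, 1.25313),
    class = "triphasic"))

.pw_state_rates <- c(rest = 70, fear = 100, exercise = 150)

rate_to_state <- function(heart_rate) {
  names(.pw_state_rates)[which.min(abs(.pw_state_rates - heart_rate))]
}

#' Cosine test waveform
#'
#' The canonical single-harmonic test input: a cosine-modulated mean
#' velocity `u(t) = mean + amplitude * cos(2 pi t / period)`, defaulting to
#' a time-averaged mean of 20 cm/s over a 1.0 s cycle.  Its spectrum has
#' exactly two non-zero coefficients (B0 and B1), which makes every stage
#' of the reconstruction checkable by hand.
#'
#' @param mean Time-averaged mean velocity in m/s.
#' @param amplitude Cosine amplitude in m/s.
#' @param period Cycle period in s.
#' @param n Number of uniform samples on `[0, period)` (>= 16).
#' @param mode Waveform mode, `"mean"` or `"centerline"`.
#' @return A `vel_waveform`.
#' @examples
#' synth_cosine()
#' @export
synth_cosine <- function(mean = 0.20, amplitude = 0.05, period = 1.0,
                         n = 256L, mode = "mean") {
  if (n < 16L) pw_input_error("`n` must be at least 16")
  t <- seq(0, period, length.out = n + 1L)[seq_len(n)]
  waveform(t, mean + amplitude * cos(2 * pi * t / period), period = period,
           mode = mode, label = "cosine")
}

#' Synthetic physiologic velocity waveform
#'
#' Generates a deterministic multi-harmonic waveform from a named template
#' (`"carotid_like"`, `"brachial_like"`, `"femoral_like"`) at a given heart
#' rate.  The carotid-like template is monophasic (velocity never
#' negative); the brachial- and femoral-like templates are triphasic (a
#' reverse-flow phase follows systole).  These shape classes are asserted
#' after generation and violating them is an error.  When `mean_velocity`
#' is omitted it is derived from the template's per-state Reynolds number
#' (states resolved from the heart rate: rest 70, fear 100, exercise
#' 150 beats/min) and the template vessel of [template_vessel()].
#'
#' @param name Template name.
#' @param heart_rate Heart rate in beats/min.
#' @param mean_velocity Cycle-mean velocity in m/s; default derived from
#'   the template's state table.
#' @param n Samples per cycle.
#' @param jitter Relative amplitude of optional seeded high-harmonic
#'   jitter (0 disables; used for robustness experiments).
#' @param seed Integer seed for the jitter; required when `jitter > 0`.
#' @return A `vel_waveform` in mean mode.
#' @examples
#' synth_template("brachial_like", heart_rate = 70)
#' @export
synth_template <- function(name = c("carotid_like", "brachial_like",
                                    "femoral_like"),
                           heart_rate = 70, mean_velocity = NULL,
                           n = 256L, jitter = 0, seed = NULL) {
  name <- match.arg(name)
  if (heart_rate <= 0) pw_input_error("`heart_rate` must be positive")
  tpl <- .pw_templates[[name]]
  period <- 60 / heart_rate
  if (is.null(mean_velocity)) {
    ves <- template_vessel(name)
    re <- tpl$reynolds[[rate_to_state(heart_rate)]]
    mean_velocity <- re * ves$viscosity / (2 * ves$radius * ves$density)
  }
  t <- seq(0, period, length.out = n + 1L)[seq_len(n)]
  u <- rep(1, n)
  for (k in seq_along(tpl$amp)) {
    u <- u + tpl$amp[k] * cos(2 * pi * k * t / period + tpl$phase[k])
  }
  if (jitter > 0) {
    if (is.null(seed)) pw_input_error("`seed` is required when jitter > 0")
    rng <- local({set.seed(seed); list(a = stats::runif(6, 0, jitter),
                                       p = stats::runif(6, -pi, pi))})
    for (k in 1:6) {
      u <- u + rng$a[k] * cos(2 * pi * (12 + k) * t / period + rng$p[k])
    }
  }
  u <- u * mean_velocity
  w <- waveform(t, u, period = period, mode = "mean", label = name)
  if (tpl$class == "monophasic" && min(u) < 0) {
    pw_numeric_error(sprintf(
      "template '%s' generated a negative velocity (min %.3g); monophasic invariant violated",
      name, min(u)))
  }
  if (tpl$class == "triphasic" && !(min(u) < 0 && mean(u) > 0)) {
    pw_numeric_error(sprintf(
      "template '%s' must be triphasic (min < 0 < mean); got min %.3g, mean %.3g",
      name, min(u), mean(u)))
  }
  w
}

#' Template vessel specification
#'
#' The vessel paired with each waveform template, with radius chosen so
#' that the rest-state (70 beats/min) Womersley number is the template's
#' nominal value (4.3 carotid-like, 4.2 brachial-like, 4.8 femoral-like)
#' with default blood properties.
#'
#' @inheritParams synth_template
#' @return A [vessel_spec()].
#' @export
template_vessel <- function(name = c("carotid_like", "brachial_like",
                                     "femoral_like")) {
  name <- match.arg(name)
  tpl <- .pw_templates[[name]]
  omega_rest <- 2 * pi * 70 / 60
  radius <- tpl$alpha_rest / sqrt(omega_rest * 1060 / 4.5e-3)
  vessel_spec(radius = radius)
}

#' Summary of the built-in templates
#'
#' @return A tibble with one row per template: name, shape class, vessel
#'   diameter (m), rest-state Womersley number, and per-state mean
#'   velocities (m/s).
#' @export
template_defaults <- function() {
  purrr::map_dfr(names(.pw_templates), function(nm) {
    tpl <- .pw_templates[[nm]]
    ves <- template_vessel(nm)
    means <- tpl$reynolds * ves$viscosity / (2 * ves$radius * ves$density)
    tibble(name = nm, class = tpl$class, diameter = 2 * ves$radius,
           alpha_rest = tpl$alpha_rest,
           mean_rest = means[["rest"]], mean_fear = means[["fear"]],
           mean_exercise = means[["exercise"]])
  })
}

#' Generate one waveform per cardiovascular state
#'
#' Maps a template across heart rates (default the rest / fear / exercise
#' rates 70, 100, 150 beats/min), yielding one waveform per rate with
#' period `60/rate` s; the Womersley number downstream grows as the square
#' root of the rate for a fixed vessel.
#'
#' @inheritParams synth_template
#' @param rates Heart rates in beats/min.
#' @return A named list of `vel_waveform`s (names `"<rate>bpm"`).
#' @export
sweep_states <- function(name, rates = c(70, 100, 150), n = 256L) {
  if (length(rates) == 0) return(list())
  if (any(rates <= 0)) pw_input_error("heart rates must be positive")
  out <- lapply(rates, function(rt) synth_template(name, heart_rate = rt,
                                                   n = n))
  stats::setNames(out, paste0(rates, "bpm"))
}
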