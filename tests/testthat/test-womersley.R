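# the velocity-driven Womersley solution

test_that("the Womersley number follows its defining formula", {
  ves <- test_vessel(radius = 2e-3)
  a <- womersley_number(ves, period = 60 / 70)
  expect_equal(a, 2e-3 * sqrt((2 * pi * 70 / 60) * 1060 / 4.5e-3),
               tolerance = 1e-12)
  expect_equal(round(a, 2), 2.63)
  # limits and scalings
  expect_equal(womersley_number(ves, omega = 0), 0)
  expect_equal(womersley_number(test_vessel(4e-3), period = 1),
               2 * womersley_number(test_vessel(2e-3), period = 1))
  expect_equal(womersley_number(ves, period = 1, n = 4),
               2 * womersley_number(ves, period = 1))
})

test_that("harmonic factors use the e^(i 3 pi/4) branch and reduce to the parabolic limit", {
  ves <- vessel_with_alpha(4.2)
  hf <- harmonic_factors(ves, 2 * pi, 1:3)
  expect_equal(Arg(hf$lambda), rep(3 * pi / 4, 3))
  expect_equal(Mod(hf$lambda), 4.2 * sqrt(1:3), tolerance = 1e-12)
  expect_true(all(Mod(hf$shape_denominator) > 0))
  expect_true(all(Mod(hf$shape_denominator) < 2))

  # alpha -> 0: shape function tends to the parabola 2(1 - (r/R)^2);
  # oracle from the small-argument series J0(z) ~ 1 - z^2/4 + z^4/64
  ves0 <- vessel_with_alpha(0.01)
  hf0 <- harmonic_factors(ves0, 2 * pi, 1)
  rr <- seq(0, 1, length.out = 11)
  shape <- (1 - pulsewss:::besselj0_ratio(hf0$lambda, rr)) /
    hf0$shape_denominator
  expect_lt(max(Mod(shape - 2 * (1 - rr^2))), 1e-3)
  # antegrade-positive wall factor over the denominator tends to +4/R,
  # the quasi-steady value (series: L J1/J0 ~ L^2/2, denom ~ -L^2/8)
  expect_lt(Mod(hf0$wall_gradient_factor / hf0$shape_denominator -
                  4 / ves0$radius), 1e-3 / ves0$radius)
})

test_that("profiles satisfy no-slip and recover the driving waveform as area-mean", {
  ves <- test_vessel()
  w <- bandlimited_waveform()
  p <- womersley_profile(w, ves, n_harmonics = 5)
  U <- pulsewss:::profile_matrix(p)
  expect_lt(max(abs(U[nrow(U), ])), 1e-10 * max(abs(U)))
  am <- area_mean_waveform(p)
  ref <- reconstruct_waveform(fourier_spectrum(w, 5), time = am$time)
  expect_lt(max_rel_err(am$velocity, ref$velocity), 1e-3)
})

test_that("constant input gives exactly the steady Poiseuille solution", {
  ves <- test_vessel()
  w <- synth_cosine(amplitude = 0)
  p <- womersley_profile(w, ves)
  r <- attr(p, "r_grid")
  expected <- 2 * 0.2 * (1 - (r / ves$radius)^2)
  U <- pulsewss:::profile_matrix(p)
  expect_lt(max(abs(U - expected)), 1e-12)
  # WSS is 4 mu U / R = 1.8 Pa throughout
  tau <- womersley_wss(w, ves)
  expect_equal(tau$wss, rep(1.8, 200), tolerance = 1e-12)
})

test_that("analytic flow rate equals quadrature of the profile and pi R^2 U", {
  ves <- test_vessel()
  w <- bandlimited_waveform()
  p <- womersley_profile(w, ves, n_harmonics = 5)
  qa <- womersley_flow(w, ves, time = attr(p, "t_grid"), n_harmonics = 5)
  qn <- numeric_flow(p)
  expect_lt(max_rel_err(qa$flow, qn$flow), 1e-3)
  # steady value: U = 0.2 m/s in R = 2 mm gives 2.513e-6 m^3/s
  q0 <- womersley_flow(synth_cosine(amplitude = 0), ves)
  expect_equal(q0$flow[1], pi * (2e-3)^2 * 0.2, tolerance = 1e-12)
  expect_equal(round(q0$flow[1] * 1e6, 3), 2.513)
})

test_that("analytic WSS matches the wall finite difference of the profile", {
  ves <- vessel_with_alpha(4.2)
  w <- bandlimited_waveform()
  r_fine <- seq(0, ves$radius, length.out = 801)
  p <- womersley_profile(w, ves, r = r_fine, n_harmonics = 5)
  tau_fd <- numeric_wss(p, ves)
  tau_an <- womersley_wss(w, ves, time = attr(p, "t_grid"),
                          n_harmonics = 5)
  expect_lt(max(abs(tau_an$wss - tau_fd$wss)) / max(abs(tau_an$wss)),
            5e-3)
})

test_that("the solution is linear in the driving spectrum", {
  ves <- vessel_with_alpha(3)
  t <- pulsewss:::default_time_grid(1)
  s1 <- as_spectrum(c(0.1, 0.05 + 0.01i, 0 + 0i), period = 1)
  s2 <- as_spectrum(c(0.05, -0.02i, 0.01 + 0.02i), period = 1)
  s12 <- as_spectrum(c(0.15, 0.05 - 0.01i, 0.01 + 0.02i), period = 1)
  tau1 <- womersley_wss(s1, ves, time = t)
  tau2 <- womersley_wss(s2, ves, time = t)
  tau12 <- womersley_wss(s12, ves, time = t)
  expect_equal(tau12$wss, tau1$wss + tau2$wss, tolerance = 1e-12)
})

test_that("wss converges to quasi-steady Poiseuille as alpha -> 0", {
  ves <- vessel_with_alpha(0.1)
  w <- synth_cosine()
  tau_w <- womersley_wss(w, ves)
  tau_p <- poiseuille_wss(w, ves)
  expect_lt(max(abs(tau_w$wss - tau_p$wss)) / max(abs(tau_p$wss)), 0.01)
  p_w <- womersley_profile(w, ves)
  p_p <- poiseuille_profile(w, ves)
  expect_lt(max(abs(p_w$velocity - p_p$velocity)) /
              max(abs(p_p$velocity)), 0.01)
})

test_that("centerline-mode input is rescaled so U(0, t) reproduces the measurement", {
  ves <- vessel_with_alpha(4)
  w <- bandlimited_waveform()
  w_cl <- waveform(w$time, w$velocity, period = 1, mode = "centerline")
  s <- fourier_spectrum(w_cl, n_harmonics = 5)
  sm <- centerline_to_mean(s, ves)
  expect_equal(sp_mode(sm), "mean")
  expect_equal(Re(sm$b[sm$n == 0]), Re(s$b[s$n == 0]) / 2)
  p <- womersley_profile(sm, ves)
  U0 <- pulsewss:::profile_matrix(p)[1, ]   # r = 0 row
  ref <- reconstruct_waveform(s, time = attr(p, "t_grid"))
  expect_lt(max_rel_err(U0, ref$velocity), 1e-8)
  # alpha -> 0: every rescale factor approaches the parabolic value 2
  ves0 <- vessel_with_alpha(0.05)
  hf0 <- harmonic_factors(ves0, 2 * pi, 1:3)
  factor <- hf0$centerline_factor / hf0$shape_denominator
  expect_lt(max(Mod(factor - 2)), 1e-3)
  # profile functions accept centerline waveforms directly
  p2 <- womersley_profile(w_cl, ves, n_harmonics = 5)
  expect_lt(max_rel_err(pulsewss:::profile_matrix(p2)[1, ], ref$velocity),
            1e-8)
})

test_that("the pressure-driven comparator matches classical limits and the velocity-driven loop", {
  ves <- vessel_with_alpha(4)
  # steady gradient only: Poiseuille with U_mean = G0 R^2 / (8 mu)
  g0 <- 50
  ps <- pressure_profile(as_spectrum(c(g0, 0), period = 1), ves)
  u_mean <- g0 * ves$radius^2 / (8 * ves$viscosity)
  U <- pulsewss:::profile_matrix(ps)
  rr <- attr(ps, "r_grid") / ves$radius
  expect_lt(max(abs(U - 2 * u_mean * (1 - rr^2))), 1e-10 * u_mean)

  # round trip: pressure-driven profile -> area-mean -> velocity-driven
  pg <- as_spectrum(c(40, 25 * exp(0.4i), 10 * exp(-1.1i)), period = 1)
  p1 <- pressure_profile(pg, ves)
  am <- area_mean_waveform(p1)
  p2 <- womersley_profile(fourier_spectrum(am, n_harmonics = 2), ves,
                          r = attr(p1, "r_grid"),
                          time = attr(p1, "t_grid"))
  expect_lt(max(abs(p1$velocity - p2$velocity)) / max(abs(p1$velocity)),
            5e-3)

  # zero gradient gives zero flow
  p0 <- pressure_profile(as_spectrum(c(0, 0), period = 1), ves)
  expect_equal(max(abs(p0$velocity)), 0)
})

test_that("degenerate and invalid inputs error informatively", {
  ves <- test_vessel()
  expect_error(harmonic_factors(ves, 2 * pi, 0), "n.*>= 1",
               class = "pw_input_error")
  expect_error(
    womersley_profile(bandlimited_waveform(), ves,
                      r = c(0, 3e-3), n_harmonics = 5),
    "within", class = "pw_input_error")
  s_mean <- fourier_spectrum(bandlimited_waveform(), 5)
  expect_error(centerline_to_mean(s_mean, ves), "centerline",
               class = "pw_input_error")
})
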