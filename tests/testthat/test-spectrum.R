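# one-sided Fourier decomposition and reconstruction

test_that("single-harmonic and constant signals decompose exactly", {
  s <- fourier_spectrum(synth_cosine(n = 256), n_harmonics = 20)
  expect_equal(Re(s$b[s$n == 0]), 0.20, tolerance = 1e-12)
  expect_lt(Mod(s$b[s$n == 1] - (0.05 + 0i)), 1e-12)
  expect_lt(max(Mod(s$b[s$n >= 2])), 1e-12)

  sc <- fourier_spectrum(synth_cosine(amplitude = 0, n = 64),
                         n_harmonics = 10)
  expect_equal(Re(sc$b[sc$n == 0]), 0.20, tolerance = 1e-12)
  expect_lt(max(Mod(sc$b[sc$n >= 1])), 1e-14)
})

test_that("a pure second harmonic sine gives B2 = -A*i under the one-sided convention", {
  period <- 1
  m <- 128
  t <- seq(0, period, length.out = m + 1)[seq_len(m)]
  u <- 0.1 * sin(2 * (2 * pi / period) * t)
  s <- fourier_spectrum(waveform(t, u, period = period), n_harmonics = 5)
  # independent oracle: direct DFT summation at n = 2
  b2_direct <- 2 / m * sum(u * exp(-1i * 2 * (2 * pi / period) * t))
  expect_lt(Mod(b2_direct - (0 - 0.1i)), 1e-12)
  expect_lt(Mod(s$b[s$n == 2] - b2_direct), 1e-12)
  expect_lt(abs(Re(s$b[s$n == 0])), 1e-14)
  expect_lt(max(Mod(s$b[!s$n %in% c(0, 2)])), 1e-12)
})

test_that("decompose -> reconstruct is the identity for band-limited signals", {
  w <- bandlimited_waveform(n = 256)
  s <- fourier_spectrum(w, n_harmonics = 5)
  back <- reconstruct_waveform(s, time = w$time)
  expect_lt(max(abs(back$velocity - w$velocity)), 1e-10)
  # also with the default 20 harmonics (extra coefficients are ~0)
  s20 <- fourier_spectrum(w, n_harmonics = 20)
  back20 <- reconstruct_waveform(s20, time = w$time)
  expect_lt(max(abs(back20$velocity - w$velocity)), 1e-10)
  # time-mean of the reconstruction equals B0
  expect_lt(abs(mean(back$velocity) - Re(s$b[s$n == 0])), 1e-12)
})

test_that("reconstruction special cases behave", {
  s <- fourier_spectrum(synth_cosine(), n_harmonics = 3)
  # cosine peak at t = 0 is mean + amplitude
  expect_equal(reconstruct_waveform(s, time = 0)$velocity, 0.25,
               tolerance = 1e-10)
  zero <- as_spectrum(c(0, 0, 0), period = 1)
  expect_equal(reconstruct_waveform(zero)$velocity, rep(0, 200))
})

test_that("the Nyquist precondition is enforced and auto-resampling lifts it", {
  w4 <- waveform(c(0, 0.25, 0.5, 0.75), c(0.2, 0.25, 0.2, 0.15),
                 period = 1)
  expect_error(fourier_spectrum(w4, n_harmonics = 20, resample = "never"),
               "M >= 2N", class = "pw_input_error")
  s <- fourier_spectrum(w4, n_harmonics = 20)   # resamples internally
  expect_equal(max(s$n), 20)
  # non-uniform sampling is accepted through the same path
  withr::local_seed(42)
  t_nonuni <- sort(c(0, 0.07, cumsum(stats::runif(40, 0.01, 0.03))))
  t_nonuni <- t_nonuni[t_nonuni < 0.95]
  u <- 0.2 + 0.05 * cos(2 * pi * t_nonuni)
  wn <- waveform(t_nonuni, u, period = 1)
  sn <- fourier_spectrum(wn, n_harmonics = 5)
  expect_lt(Mod(sn$b[sn$n == 1] - 0.05), 5e-3)
})

test_that("linear drift is removed before decomposition", {
  t <- seq(0, 1, length.out = 129)[-129]
  drift <- 0.03 * t
  w <- waveform(t, 0.2 + 0.05 * cos(2 * pi * t) + drift, period = 1)
  s <- fourier_spectrum(w, n_harmonics = 10)
  # without detrending the sawtooth drift leaks ~ 0.03/(pi n) into every
  # harmonic; detrended, harmonics beyond the first stay clean
  expect_lt(max(Mod(s$b[s$n >= 2])), 1e-3)
  s_raw <- fourier_spectrum(w, n_harmonics = 10, detrend = FALSE)
  expect_gt(max(Mod(s_raw$b[s_raw$n >= 2])), 1e-3)
})

test_that("spectrum export and tidy round-trip the coefficients", {
  s <- fourier_spectrum(bandlimited_waveform(), n_harmonics = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(s, path)
  back <- utils::read.csv(path)
  expect_equal(complex(real = back$re, imaginary = back$im), s$b,
               tolerance = 1e-12)
  td <- tidy(s)
  expect_equal(td$modulus, Mod(s$b))
  expect_equal(nrow(td), 6)
})
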