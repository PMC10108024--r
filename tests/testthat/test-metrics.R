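# oscillatory shear index, cycle summaries and method comparison

make_series <- function(f, n = 256, period = 1, method = "womersley") {
  t <- seq(0, period, length.out = n + 1)[seq_len(n)]
  pulsewss:::new_wss_series(t, f(t), period = period, method = method)
}

test_that("OSI hits its closed-form values", {
  # zero-mean sinusoid: purely oscillatory, the theoretical maximum 0.5
  s_sin <- make_series(function(t) sin(2 * pi * t))
  expect_equal(osi(s_sin), 0.5, tolerance = 1e-12)
  # never-negative shear: 0
  s_pos <- make_series(function(t) 1 + 0.5 * sin(2 * pi * t))
  expect_equal(osi(s_pos), 0, tolerance = 1e-12)
  # piecewise +2 / -1 over half cycles: |int| = T/2, int|.| = 3T/2,
  # hand integration gives 0.5 * (1 - 1/3) = 1/3
  s_pw <- make_series(function(t) ifelse(t < 0.5, 2, -1), n = 2000)
  expect_equal(osi(s_pw), 1 / 3, tolerance = 2e-3)
  # degenerate all-zero signal
  expect_equal(osi(make_series(function(t) 0 * t)), 0)
})

test_that("OSI is scale-invariant, sign-symmetric and increases with reversal", {
  s <- make_series(function(t) 0.8 + sin(2 * pi * t) + 0.3 * cos(4 * pi * t))
  base <- osi(s)
  s_scaled <- make_series(function(t) 7 * (0.8 + sin(2 * pi * t) +
                                             0.3 * cos(4 * pi * t)))
  expect_equal(osi(s_scaled), base, tolerance = 1e-12)
  s_neg <- make_series(function(t) -(0.8 + sin(2 * pi * t) +
                                       0.3 * cos(4 * pi * t)))
  expect_equal(osi(s_neg), base, tolerance = 1e-12)
  # adding a reversing zero-mean component to non-reversing shear
  # strictly increases OSI from zero
  s_mono <- make_series(function(t) 1 + 0.3 * sin(2 * pi * t))
  expect_equal(osi(s_mono), 0)
  s_rev <- make_series(function(t) 1 + 2.4 * sin(2 * pi * t))
  expect_gt(osi(s_rev), 0)
})

test_that("cycle summaries match brute-force recomputation", {
  # constant signal
  sc <- make_series(function(t) rep(1.8, length(t)))
  sm <- wss_summary(sc)
  expect_equal(sm$peak_wss, 1.8)
  expect_equal(sm$min_wss, 1.8)
  expect_equal(sm$time_avg_wss, 1.8, tolerance = 1e-12)
  expect_equal(sm$time_median_wss, 1.8)
  expect_equal(sm$osi, 0)
  # pure sinusoid of amplitude A
  ss <- make_series(function(t) 2.5 * sin(2 * pi * t))
  sms <- wss_summary(ss)
  expect_equal(sms$peak_wss, 2.5, tolerance = 1e-3)
  expect_equal(sms$min_wss, -2.5, tolerance = 1e-3)
  expect_lt(abs(sms$time_avg_wss), 1e-12)
  expect_equal(sms$osi, 0.5, tolerance = 1e-12)
  # triphasic synthetic waveform against direct sample statistics
  tau <- womersley_wss(synth_template("femoral_like"),
                       template_vessel("femoral_like"))
  smf <- wss_summary(tau)
  expect_equal(smf$peak_wss, max(tau$wss))
  expect_equal(smf$min_wss, min(tau$wss))
  expect_equal(smf$time_median_wss, stats::median(tau$wss))
  dt <- diff(tau$time[1:2])
  expect_equal(smf$time_avg_wss, mean(tau$wss),
               tolerance = 1e-10)  # uniform periodic grid: mean = integral/T
  expect_true(smf$min_wss <= smf$time_avg_wss,
              smf$time_avg_wss <= smf$peak_wss)
})

test_that("method comparison percentages are Womersley-referenced and signed", {
  ves <- template_vessel("brachial_like")
  w <- synth_template("brachial_like")
  sw <- wss_summary(womersley_wss(w, ves))
  sp <- wss_summary(poiseuille_wss(w, ves))
  cmp <- compare_methods(sp, sw)
  expect_equal(cmp$pct_diff_peak,
               100 * (sw$peak_wss - sp$peak_wss) / sw$peak_wss)
  expect_equal(cmp$pct_diff_median,
               100 * (sp$time_median_wss - sw$time_median_wss) /
                 sw$time_median_wss)
  expect_equal(cmp$delta_osi, sw$osi - sp$osi)
  # identical summaries give all zeros
  cmp0 <- compare_methods(sw, sw)
  expect_equal(cmp0$pct_diff_peak, 0)
  expect_equal(cmp0$pct_diff_median, 0)
  expect_equal(cmp0$delta_osi, 0)
  # swapping arguments flips the sign of the symmetric-difference field
  cmp_rev <- compare_methods(sw, sp)
  expect_equal(cmp_rev$delta_osi, -cmp$delta_osi)
  # a zero Womersley reference is flagged, not NaN-propagated
  zero <- wss_summary(make_series(function(t) 0 * t))
  expect_warning(cmpz <- compare_methods(sp, zero), "zero")
  expect_true(cmpz$undefined)
  expect_true(is.na(cmpz$pct_diff_peak))
})
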