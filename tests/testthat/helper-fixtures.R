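# shared fixtures: small vessels and waveforms used across test files

test_vessel <- function(radius = 2e-3) vessel_spec(radius = radius)

# a vessel whose fundamental Womersley number is exactly `alpha` at the
# given period, with default blood properties
vessel_with_alpha <- function(alpha, period = 1) {
  vessel_spec(radius = alpha / sqrt((2 * pi / period) * 1060 / 4.5e-3))
}

# band-limited multi-harmonic waveform with known coefficients
bandlimited_waveform <- function(b0 = 0.2,
                                 b = c(0.05 + 0.02i, -0.01 + 0.03i,
                                       0.015 - 0.005i, 0.004 + 0.008i,
                                       -0.006 + 0.002i),
                                 period = 1, n = 256) {
  t <- seq(0, period, length.out = n + 1)[seq_len(n)]
  u <- rep(b0, n)
  for (k in seq_along(b)) {
    u <- u + Re(b[k] * exp(1i * k * 2 * pi * t / period))
  }
  waveform(t, u, period = period, label = "bandlimited")
}

# write a waveform as a two-column CSV and return the path
write_temp_csv <- function(df, header = TRUE, sep = ",") {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     col.names = header, quote = FALSE)
  path
}

max_rel_err <- function(x, ref) max(abs(x - ref)) / max(abs(ref))
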