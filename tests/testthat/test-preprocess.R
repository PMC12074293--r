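test_that("gap filling follows the policy and preserves length", {
  s <- random_series(20)
  expect_identical(fill_gaps(s), s)  # no gaps -> identity
  t <- (0:4) / FS
  g <- accel_series(t, c(1, 1, NA, 3, 3), c(0, 0, NA, 0, 0),
                    c(1, 3, NA, 1, 3),
                    gap_mask = c(FALSE, FALSE, TRUE, FALSE, FALSE),
                    nominal_rate_hz = FS)
  lin <- fill_gaps(g, "linear_interpolation")
  expect_equal(lin$x[3], 2)        # midpoint of 1 and 3
  expect_equal(lin$z[3], 2)
  expect_length(lin, 5)
  hold <- fill_gaps(g, "hold_last")
  expect_equal(hold$x[3], 1)
  expect_equal(hold$z[3], 3)
  allbad <- accel_series(t, rep(NA_real_, 5), rep(NA_real_, 5),
                         rep(NA_real_, 5), gap_mask = rep(TRUE, 5),
                         nominal_rate_hz = FS)
  expect_error(fill_gaps(allbad), "all samples")
})

test_that("1% random masking leaves the dominant frequency unchanged", {
  cfg <- sim_config(tremor_frequency_hz = 5, tremor_amplitude = 1,
                    noise_sigma = 0.05, duration_s = 60, seed = 12)
  s <- simulate_tremor(cfg)
  set.seed(42)
  idx <- sample(length(s), round(0.01 * length(s)))
  s$gap_mask[idx] <- TRUE
  f_masked <- dominant_frequency(
    compute_spectra(run_preprocess(s)))$dominant_frequency_hz
  expect_lt(abs(f_masked - 5), 0.02)
})

test_that("detrending removes lines exactly and spares tones", {
  t <- (0:999) / FS
  ramp <- accel_series(t, 2 + 3 * t, -1 - 0.5 * t, 0.1 * t,
                       nominal_rate_hz = FS)
  d <- detrend_series(ramp)
  expect_lt(max(abs(c(d$x, d$y, d$z))), 1e-10)
  expect_lt(max(abs(colMeans(cbind(d$x, d$y, d$z)))), 1e-12)
  # tone + ramp: tone amplitude preserved within 0.1 %
  s <- tone_series(5, 1, duration_s = 30)
  s$z <- s$z + 2 + 0.3 * s$timestamps
  dz <- detrend_series(s)
  amp <- tone_amplitude(dz, 5)
  expect_equal(amp, 1, tolerance = 1e-3)
  expect_error(detrend_series(accel_series(0, 1, 1, 1)), ">= 2 samples")
})

test_that("the high-pass rejects DC and passes the tremor band", {
  n <- 2000
  t <- (0:(n - 1)) / FS
  const <- accel_series(t, rep(9.81, n), rep(9.81, n), rep(9.81, n),
                        nominal_rate_hz = FS)
  f <- bandpass_filter(const)
  expect_lt(max(abs(c(f$x, f$y, f$z))), 1e-3)
  # 5 Hz unit tone passes within 1 % (oracle: squared Butterworth response)
  s <- tone_series(5, 1, duration_s = 36)
  out <- bandpass_filter(s)
  got <- tone_amplitude(out, 5)
  want <- butter_gain(4, 1, FS, 5, "high", zero_phase = TRUE) *
    butter_gain(4, 15, FS, 5, "low", zero_phase = TRUE)
  expect_equal(got, want, tolerance = 0.01)
  expect_lt(abs(got - 1), 0.01)
})

test_that("0.2 Hz drift power drops by >= 99% while a 5 Hz tone survives", {
  n <- floor(60 * FS)
  t <- (0:(n - 1)) / FS
  z <- sin(2 * pi * 0.2 * t) + sin(2 * pi * 5 * t)
  s <- accel_series(t, numeric(n), numeric(n), z, nominal_rate_hz = FS)
  out <- bandpass_filter(s)
  # joint least-squares fit separates the two components exactly
  core <- seq(floor(n / 4), floor(3 * n / 4))
  M <- cbind(sin(2 * pi * 0.2 * t[core]), cos(2 * pi * 0.2 * t[core]),
             sin(2 * pi * 5 * t[core]), cos(2 * pi * 5 * t[core]))
  cf <- qr.solve(M, out$z[core])
  drift_gain <- sqrt(sum(cf[1:2]^2))
  tone_gain <- sqrt(sum(cf[3:4]^2))
  expect_lt(drift_gain^2, 0.01)  # >= 99 % power reduction
  # transfer-function oracle at 0.2 Hz bounds the residual
  oracle <- butter_gain(4, 1, FS, 0.2, "high", zero_phase = TRUE)
  expect_lt(drift_gain, oracle + 1e-3)
  expect_equal(tone_gain, 1, tolerance = 0.01)
})

test_that("tremor-band tones pass nearly unattenuated", {
  # < 2 % attenuation through 3-10 Hz; at 12 Hz the default 15 Hz
  # low-pass shoulder costs ~6 %, exactly as the transfer-function
  # oracle predicts (the band edge sits too close for a 4th-order
  # zero-phase low-pass to do better)
  for (f0 in c(3, 5, 8, 10)) {
    s <- tone_series(f0, 1, duration_s = 30)
    out <- bandpass_filter(s)
    expect_gt(tone_amplitude(out, f0), 0.98)
  }
  s12 <- tone_series(12, 1, duration_s = 30)
  got <- tone_amplitude(bandpass_filter(s12), 12)
  want <- butter_gain(4, 1, FS, 12, "high", zero_phase = TRUE) *
    butter_gain(4, 15, FS, 12, "low", zero_phase = TRUE)
  expect_equal(got, want, tolerance = 0.01)
})

test_that("run_preprocess composes the stages in order", {
  cfg <- scenario_preset(1, "mild", seed = 4)
  s <- simulate_tremor(cfg)
  out <- run_preprocess(s)
  expect_lt(max(abs(colMeans(cbind(out$x, out$y, out$z)))), 1e-9)
  expect_length(out, length(s))
  expect_true(any(grepl("^detrend$", out$processing_log)))
  expect_true(any(grepl("^bandpass", out$processing_log)))
  expect_true(any(grepl("^normalize", out$processing_log)))
  # deterministic
  expect_identical(run_preprocess(s)$z, out$z)
  # g-unit input is converted first (and logged as the first stage)
  sg <- convert_units(s, "g")
  outg <- run_preprocess(sg)
  first_new <- setdiff(outg$processing_log, sg$processing_log)[1]
  expect_identical(first_new, "convert_units:m_per_s2")
  expect_equal(outg$z, out$z, tolerance = 1e-9)
})

test_that("recovered frequency is insensitive to drift amplitude", {
  f_for_drift <- function(da) {
    cfg <- sim_config(tremor_frequency_hz = 4.7, tremor_amplitude = 1,
                      drift_amplitude = da, drift_frequency_hz = 0.3,
                      noise_sigma = 0.05, duration_s = 60, seed = 31)
    sp <- compute_spectra(run_preprocess(simulate_tremor(cfg)))
    dominant_frequency(sp)$dominant_frequency_hz
  }
  expect_equal(f_for_drift(0), f_for_drift(1), tolerance = 1e-3)
})

test_that("config invariants are enforced", {
  expect_error(preprocess_config(highpass_cutoff_hz = 0), "highpass")
  expect_error(preprocess_config(lowpass_cutoff_hz = 0.5), "lowpass")
  expect_error(preprocess_config(filter_order = 0), "order")
  s <- tone_series(5, 1, duration_s = 10)
  expect_error(
    bandpass_filter(s, preprocess_config(lowpass_cutoff_hz = 28)),
    "Nyquist")
})
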