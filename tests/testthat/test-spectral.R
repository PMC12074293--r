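test_that("spectra have the documented normalisation", {
  # zero signal -> zero spectra
  n <- 600
  t <- (0:(n - 1)) / FS
  zero <- accel_series(t, numeric(n), numeric(n), numeric(n),
                       nominal_rate_hz = FS)
  sp0 <- compute_spectra(zero)
  expect_true(all(sp0$amplitude == 0) && all(sp0$psd == 0))
  # unit-amplitude 5 Hz tone, 60 s -> amplitude peak within 1 % of 1
  s <- tone_series(5, 1, duration_s = 60)
  sp <- compute_spectra(s)
  expect_equal(max(sp$amplitude[, "z"]), 1, tolerance = 0.01)
  expect_identical(colnames(sp$psd), c("x", "y", "z"))
})

test_that("Parseval's identity holds for every computed spectrum", {
  set.seed(33)
  for (i in 1:5) {
    s <- random_series(n = sample(200:900, 1))
    for (win in c("hann", "rectangular")) {
      sp <- compute_spectra(s, window = win)
      freq_power <- colSums(sp$psd) * sp$df_hz
      expect_equal(unname(freq_power), sp$time_power, tolerance = 1e-6)
    }
  }
})

test_that("spectra refuse unresolved gaps and too-short input", {
  s <- random_series(300)
  s$gap_mask[5] <- TRUE
  expect_error(compute_spectra(s), "unresolved gaps")
  expect_silent(compute_spectra(fill_gaps(s)))
  expect_error(compute_spectra(random_series(50)), "2 s")
})

test_that("dominant frequency finds off-bin tones via interpolation", {
  s <- tone_series(4.35, 1, duration_s = 60, axis = "z", noise = 0.01,
                   seed = 9)
  sp <- compute_spectra(s)
  dom <- dominant_frequency(sp)
  expect_identical(dom$dominant_axis, "z")
  expect_equal(dom$dominant_frequency_hz, 4.35, tolerance = 1e-3)
  # within one bin of the brute-force periodogram peak oracle
  expect_lt(abs(dom$dominant_frequency_hz -
                oracle_peak_hz(s$z, FS)), sp$df_hz)
})

test_that("the strongest axis wins and ties break x -> y -> z", {
  n <- floor(60 * FS)
  t <- (0:(n - 1)) / FS
  s <- accel_series(t, sin(2 * pi * 4 * t), 0.3 * sin(2 * pi * 8 * t),
                    numeric(n), nominal_rate_hz = FS)
  dom <- dominant_frequency(compute_spectra(s))
  expect_identical(dom$dominant_axis, "x")
  expect_equal(dom$dominant_frequency_hz, 4, tolerance = 1e-3)
  expect_equal(unname(dom$per_axis_hz["y"]), 8, tolerance = 1e-3)
  # identical tone on x and y -> x by axis order
  s2 <- accel_series(t, sin(2 * pi * 5 * t), sin(2 * pi * 5 * t),
                     numeric(n), nominal_rate_hz = FS)
  expect_identical(dominant_frequency(compute_spectra(s2))$dominant_axis,
                   "x")
})

test_that("pure noise falls below the peak-prominence floor", {
  set.seed(77)
  s <- random_series(n = floor(60 * FS))
  dom <- dominant_frequency(compute_spectra(s))
  expect_true(all(is.na(dom$per_axis_hz)))
  expect_true(is.na(dom$dominant_axis))
  expect_true(is.na(dom$dominant_frequency_hz))
})

test_that("dominant axis is equivariant under axis permutation", {
  cfg <- sim_config(tremor_frequency_hz = 6,
                    tremor_axis_weights = c(0, 0, 1),
                    noise_sigma = 0.02, duration_s = 30, seed = 14)
  s <- simulate_tremor(cfg)
  perm <- s
  perm$x <- s$z; perm$z <- s$x  # swap x and z
  d1 <- dominant_frequency(compute_spectra(run_preprocess(s)))
  d2 <- dominant_frequency(compute_spectra(run_preprocess(perm)))
  expect_identical(d1$dominant_axis, "z")
  expect_identical(d2$dominant_axis, "x")
  expect_equal(d2$dominant_frequency_hz, d1$dominant_frequency_hz)
})

test_that("energy band selection follows the 2-Hz grid", {
  grid <- energy_band_grid()
  expect_equal(grid[, "lo"], c(1, 3, 5, 7, 9, 11))
  expect_equal(grid[, "hi"] - grid[, "lo"], rep(2, 6))
  # all energy at 4.35 Hz -> [3, 5)
  s <- tone_series(4.35, 1, duration_s = 30)
  expect_equal(energy_band(compute_spectra(s)), c(3, 5))
  # preset-style tone at 5.5 Hz -> [5, 7)
  cfg <- sim_config(tremor_frequency_hz = 5.5, noise_sigma = 0.05,
                    duration_s = 60, seed = 2)
  sp <- compute_spectra(run_preprocess(simulate_tremor(cfg)))
  expect_equal(energy_band(sp), c(5, 7))
  # the band always contains the tri-axial PSD maximum (exhaustive oracle)
  tri <- rowSums(sp$psd)
  fmax <- sp$freq_hz[which.max(tri)]
  b <- energy_band(sp)
  expect_true(fmax >= b[1] && fmax < b[2])
})

test_that("exactly equal energy in two bands breaks toward the lower band", {
  sp <- compute_spectra(tone_series(4, 1, duration_s = 30))
  sp$psd[] <- 0
  sp$psd[which(sp$freq_hz >= 3 & sp$freq_hz < 5)[5], "z"] <- 1
  sp$psd[which(sp$freq_hz >= 5 & sp$freq_hz < 7)[5], "z"] <- 1
  expect_equal(energy_band(sp), c(3, 5))
})

test_that("band-average amplitude follows its definition", {
  s <- tone_series(4, 1, duration_s = 30)
  sp <- compute_spectra(s)
  band <- c(3, 5)
  sel <- sp$freq_hz >= 3 & sp$freq_hz < 5
  expect_equal(band_avg_amplitude(sp, band), mean(sp$amplitude[sel, ]))
  # single-bin tone of peak A in a k-bin band, other axes zero -> A/(3k)
  sp_syn <- sp
  sp_syn$amplitude[] <- 0
  k <- sum(sel)
  peak_bin <- which(sel)[10]
  sp_syn$amplitude[peak_bin, "z"] <- 0.9
  expect_equal(band_avg_amplitude(sp_syn, band), 0.9 / (3 * k))
  expect_equal(band_avg_amplitude(sp0 <- {
    z <- sp; z$amplitude[] <- 0; z
  }, band), 0)
  expect_error(band_avg_amplitude(sp, c(40, 42)), "outside")
})

test_that("windowed tri-axial energy follows its definition", {
  n <- floor(60 * FS)
  t <- (0:(n - 1)) / FS
  a <- 0.7
  s <- accel_series(t, rep(a, n), numeric(n), numeric(n),
                    nominal_rate_hz = FS)
  e <- total_energy(s, window_s = 1)
  # 60 windows of floor(55.56) = 55 samples
  expect_length(e, 60)
  expect_equal(e, rep(55 * a^2, 60))
  # doubling amplitude quadruples energy
  s2 <- s; s2$x <- 2 * s2$x
  expect_equal(total_energy(s2, 1), 4 * e)
  expect_error(total_energy(s, 120), "window longer")
  expect_error(total_energy(s, 0), "window_s")
})

test_that("analyze_test produces result rows and honours the missing state", {
  miss <- analyze_test(NULL, patient_id = 3, test_id = 4,
                       meta = list(age = 60, years_diagnosed = 4))
  expect_false(miss$performed)
  expect_true(is.na(miss$dom_freq_x_hz) && is.na(miss$energy_band) &&
              is.na(miss$band_avg_amplitude))
  expect_equal(miss$age, 60)

  cfg <- sim_config(tremor_frequency_hz = 4.5, tremor_amplitude = 1,
                    noise_sigma = 0.05, duration_s = 60, seed = 6)
  s <- simulate_tremor(cfg)
  row <- analyze_test(s, patient_id = 1, test_id = 1,
                      meta = list(age = 65, years_diagnosed = 5))
  expect_true(row$performed)
  expect_identical(row$energy_band, "3.0-5.0")
  expect_equal(row$dom_freq_z_hz, 4.5, tolerance = 0.01)
  expect_length(attr(row, "energy_per_window"), 60)
  # deterministic for fixed input
  row2 <- analyze_test(s, patient_id = 1, test_id = 1,
                       meta = list(age = 65, years_diagnosed = 5))
  expect_equal(row$band_avg_amplitude, row2$band_avg_amplitude)
})
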