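# Shared fixture builders. Everything is generated in code; no binary data.

FS <- 55.56

# a bare tone series without the simulator (independent construction)
tone_series <- function(f0, amplitude = 1, duration_s = 60, fs = FS,
                        axis = "z", units = "m_per_s2", noise = 0,
                        seed = NULL) {
  n <- floor(duration_s * fs)
  t <- (0:(n - 1)) / fs
  v <- amplitude * sin(2 * pi * f0 * t)
  m <- matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  m[, axis] <- v
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    m <- m + matrix(rnorm(3 * n, sd = noise), n, 3)
  }
  accel_series(t, m[, 1], m[, 2], m[, 3], units = units,
               nominal_rate_hz = fs, provenance = "helper tone")
}

random_series <- function(n = 50, fs = FS, units = "m_per_s2") {
  t <- (0:(n - 1)) / fs
  accel_series(t, rnorm(n), rnorm(n), rnorm(n), units = units,
               nominal_rate_hz = fs)
}

# brute-force periodogram peak (rectangular window, no interpolation):
# the independent oracle for dominant-frequency checks
oracle_peak_hz <- function(v, fs, band = c(1, 12)) {
  n <- length(v)
  X <- Mod(fft(v - mean(v)))[1:(floor(n / 2) + 1)]
  f <- (0:floor(n / 2)) * fs / n
  sel <- f >= band[1] & f <= band[2]
  f[sel][which.max(X[sel])]
}

fixture_patients <- function() cohort_fixture("pd_demographics.csv")
fixture_results <- function() cohort_fixture("clinical_test_results.csv")
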