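# Synthetic tri-axial recordings with known ground truth. The generator
# states the world the analysis assumes: a gravity offset along a fixed
# orientation, a tremor tone (optionally with harmonics) distributed over
# the axes by a unit weight vector, sub-1-Hz baseline drift, sub-2-Hz
# voluntary-motion sinusoids, and additive white Gaussian sensor noise.

unit_vector <- function(v, what) {
  v <- as.numeric(v)
  if (length(v) != 3 || abs(sqrt(sum(v^2)) - 1) > 1e-6) {
    stop(what, " must be a unit 3-vector", call. = FALSE)
  }
  v
}

#' Simulation configuration for a tremor recording
#'
#' Fully parameterises one synthetic recording. All amplitudes are peak
#' accelerations in m/s^2; the gravity offset is a constant 1 g
#' (9.81 m/s^2) along `gravity_orientation`.
#'
#' @param tremor_frequency_hz Tremor tone frequency in Hz; 0 disables the
#'   tone. Must respect the Nyquist limit `sampling_rate_hz / 2`.
#' @param tremor_amplitude Peak tremor acceleration, m/s^2 (>= 0).
#' @param tremor_axis_weights Unit 3-vector distributing the tone (and any
#'   drift/voluntary components) across x/y/z.
#' @param harmonics List of `c(multiple, relative_amplitude)` pairs added at
#'   integer multiples of the tremor frequency. Default none.
#' @param drift_amplitude,drift_frequency_hz Peak and frequency (< 1 Hz) of
#'   a sinusoidal baseline-drift component, applied along
#'   `gravity_orientation` (postural shift).
#' @param voluntary List of `c(frequency_hz, amplitude)` pairs (< 2 Hz)
#'   emulating writing/waving motion, applied along `tremor_axis_weights`.
#' @param gravity_orientation Unit 3-vector of the static 1 g offset.
#' @param noise_sigma White sensor-noise standard deviation, m/s^2.
#' @param duration_s Recording length in seconds (> 0).
#' @param sampling_rate_hz Samples per second (default 55.56).
#' @param seed Integer RNG seed; the same config and seed give bit-identical
#'   recordings.
#'
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(tremor_frequency_hz = 5,
                       tremor_amplitude = 1,
                       tremor_axis_weights = c(0, 0, 1),
                       harmonics = list(),
                       drift_amplitude = 0,
                       drift_frequency_hz = 0.3,
                       voluntary = list(),
                       gravity_orientation = c(0, 0, 1),
                       noise_sigma = 0.05,
                       duration_s = 60,
                       sampling_rate_hz = 55.56,
                       seed = 1L) {
  cfg <- list(
    tremor_frequency_hz = tremor_frequency_hz,
    tremor_amplitude = tremor_amplitude,
    tremor_axis_weights = unit_vector(tremor_axis_weights,
                                      "tremor_axis_weights"),
    harmonics = harmonics,
    drift_amplitude = drift_amplitude,
    drift_frequency_hz = drift_frequency_hz,
    voluntary = voluntary,
    gravity_orientation = unit_vector(gravity_orientation,
                                      "gravity_orientation"),
    noise_sigma = noise_sigma,
    duration_s = duration_s,
    sampling_rate_hz = sampling_rate_hz,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  nyq <- cfg$sampling_rate_hz / 2
  freqs <- c(cfg$tremor_frequency_hz,
             vapply(cfg$harmonics,
                    function(h) h[1] * cfg$tremor_frequency_hz, 0),
             vapply(cfg$voluntary, function(v) v[1], 0),
             if (cfg$drift_amplitude > 0) cfg$drift_frequency_hz)
  over <- freqs[freqs >= nyq]
  if (length(over)) {
    stop(sprintf("component at %.3g Hz violates the Nyquist limit %.3g Hz",
                 over[1], nyq), call. = FALSE)
  }
  if (cfg$duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  amps <- c(cfg$tremor_amplitude, cfg$drift_amplitude, cfg$noise_sigma,
            vapply(cfg$voluntary, function(v) v[2], 0))
  if (any(amps < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (cfg$drift_amplitude > 0 && cfg$drift_frequency_hz >= 1) {
    stop("drift_frequency_hz must be < 1 Hz", call. = FALSE)
  }
  for (v in cfg$voluntary) {
    if (v[1] >= 2) stop("voluntary components must be < 2 Hz", call. = FALSE)
  }
  cfg
}

# run fn with an isolated RNG stream seeded by `seed`
with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  fn()
}

#' Simulate a tri-axial tremor recording
#'
#' Generates `floor(duration_s * sampling_rate_hz)` samples of
#' gravity + tremor tone (+ harmonics) + drift + voluntary motion +
#' white Gaussian noise, in m/s^2.
#'
#' @param config A [sim_config()].
#' @return An [accel_series()] in m/s^2, with provenance recording the seed.
#' @export
simulate_tremor <- function(config) {
  cfg <- validate_sim_config(config)
  fs <- cfg$sampling_rate_hz
  n <- floor(cfg$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  tone <- rep(0, n)
  if (cfg$tremor_amplitude > 0 && cfg$tremor_frequency_hz > 0) {
    tone <- cfg$tremor_amplitude * sin(2 * pi * cfg$tremor_frequency_hz * t)
    for (h in cfg$harmonics) {
      tone <- tone + cfg$tremor_amplitude * h[2] *
        sin(2 * pi * h[1] * cfg$tremor_frequency_hz * t)
    }
  }
  for (v in cfg$voluntary) {
    tone <- tone + v[2] * sin(2 * pi * v[1] * t)
  }
  drift <- if (cfg$drift_amplitude > 0) {
    cfg$drift_amplitude * sin(2 * pi * cfg$drift_frequency_hz * t)
  } else rep(0, n)
  m <- outer(rep(STANDARD_GRAVITY, n), cfg$gravity_orientation) +
    outer(tone, cfg$tremor_axis_weights) +
    outer(drift, cfg$gravity_orientation)
  if (cfg$noise_sigma > 0) {
    noise <- with_seed(cfg$seed, function() {
      matrix(stats::rnorm(3 * n, sd = cfg$noise_sigma), ncol = 3)
    })
    m <- m + noise
  }
  accel_series(t, m[, 1], m[, 2], m[, 3], units = "m_per_s2",
               nominal_rate_hz = fs,
               provenance = sprintf("simulate_tremor(seed=%d)", cfg$seed))
}

#' Configuration for six-position calibration fixtures
#'
#' @param true_bias Per-axis additive offset in g units.
#' @param true_scale Per-axis multiplicative gain (all > 0, ~1).
#' @param noise_sigma_g White-noise SD in g (>= 0).
#' @param duration_s Seconds per orientation.
#' @param sampling_rate_hz Samples per second.
#' @param seed Integer RNG seed.
#' @return A `calibration_sim_config` list.
#' @export
calibration_sim_config <- function(true_bias = c(0, 0, 0),
                                   true_scale = c(1, 1, 1),
                                   noise_sigma_g = 0.005,
                                   duration_s = 30,
                                   sampling_rate_hz = 55.56,
                                   seed = 1L) {
  stopifnot(length(true_bias) == 3, length(true_scale) == 3)
  if (any(true_scale <= 0)) stop("scale components must be > 0", call. = FALSE)
  if (noise_sigma_g < 0) stop("noise_sigma_g must be >= 0", call. = FALSE)
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  structure(list(true_bias = as.numeric(true_bias),
                 true_scale = as.numeric(true_scale),
                 noise_sigma_g = noise_sigma_g,
                 duration_s = duration_s,
                 sampling_rate_hz = sampling_rate_hz,
                 seed = as.integer(seed)),
            class = "calibration_sim_config")
}

#' Orientation labels used for six-position calibration
#' @export
SIX_ORIENTATIONS <- c("+x", "-x", "+y", "-y", "+z", "-z")

orientation_gravity <- function(label) {
  axis <- substr(label, 2, 2)
  sgn <- if (substr(label, 1, 1) == "+") 1 else -1
  g <- c(x = 0, y = 0, z = 0)
  g[axis] <- sgn
  unname(g)
}

#' Simulate six static calibration orientations
#'
#' For each orientation the noiseless reading is
#' `scale * (gravity on the aligned axis) + bias`, in g units, emulating a
#' sensor held static on a calibration cube with each axis aligned with
#' gravity in turn.
#'
#' @param config A [calibration_sim_config()].
#' @return A named list of six [accel_series()] in g units, names
#'   `"+x", "-x", "+y", "-y", "+z", "-z"`.
#' @export
simulate_six_positions <- function(config) {
  stopifnot(inherits(config, "calibration_sim_config"))
  fs <- config$sampling_rate_hz
  n <- floor(config$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  out <- with_seed(config$seed, function() {
    lapply(SIX_ORIENTATIONS, function(lab) {
      g <- orientation_gravity(lab)
      truth <- config$true_scale * g + config$true_bias
      m <- matrix(rep(truth, each = n), ncol = 3)
      if (config$noise_sigma_g > 0) {
        m <- m + matrix(stats::rnorm(3 * n, sd = config$noise_sigma_g),
                        ncol = 3)
      }
      s <- accel_series(t, m[, 1], m[, 2], m[, 3], units = "g",
                        nominal_rate_hz = fs,
                        provenance = sprintf("simulate_six_positions(%s, seed=%d)",
                                             lab, config$seed))
      s$orientation <- lab
      s
    })
  })
  names(out) <- SIX_ORIENTATIONS
  out
}

#' Scenario presets for the six clinical tests
#'
#' Returns a [sim_config()] whose tremor regime matches what is observed
#' clinically for each test: resting tests (1, 3) place the tone in the
#' 3-7 Hz resting-tremor band; postural tests (2, 4) in 5-9 Hz; active
#' tests (5, 6: writing and waving) add sub-2-Hz voluntary components.
#' Controls use a low-amplitude 3-6 Hz physiological tremor.
#'
#' @param test_id Clinical test number, 1-6 (1/3 resting seated/standing,
#'   2/4 postural seated/standing, 5 writing, 6 waving).
#' @param severity One of `"control"`, `"mild"`, `"strong"`.
#' @param seed Integer seed; determines both the drawn tremor frequency and
#'   the noise stream of the resulting recording.
#' @return A [sim_config()].
#' @export
scenario_preset <- function(test_id, severity = c("mild", "strong", "control"),
                            seed = 1L) {
  severity <- match.arg(severity)
  if (!test_id %in% 1:6) {
    stop("unknown test_id (must be 1..6): ", test_id, call. = FALSE)
  }
  band <- if (severity == "control") c(3, 6)
          else if (test_id %in% c(1, 3)) c(3, 7)
          else if (test_id %in% c(2, 4)) c(5, 9)
          else c(3, 8)
  amplitude <- switch(severity, control = 0.3, mild = 0.8, strong = 2.0)
  f0 <- with_seed(as.integer(seed) + 1000L * test_id, function() {
    stats::runif(1, band[1], band[2])
  })
  voluntary <- if (test_id %in% c(5, 6) && severity != "control") {
    list(c(1.0, 0.8 * amplitude), c(0.6, 0.4 * amplitude))
  } else {
    list()
  }
  sim_config(tremor_frequency_hz = f0,
             tremor_amplitude = amplitude,
             tremor_axis_weights = c(0.4, 0.4, sqrt(1 - 2 * 0.4^2)),
             drift_amplitude = if (test_id %in% c(2, 4, 5, 6)) 0.3 else 0.1,
             drift_frequency_hz = 0.3,
             voluntary = voluntary,
             gravity_orientation = c(0, 0, 1),
             noise_sigma = 0.05,
             duration_s = 60,
             sampling_rate_hz = 55.56,
             seed = seed)
}
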