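# Six-position static calibration. Sensor model per axis:
#   measured = scale * true + bias          (g units)
# With the axis aligned parallel and anti-parallel to gravity the
# time-averaged readings m+ and m- give the closed-form two-point solution
#   bias  = (m+ + m-) / 2,   scale = (m+ - m-) / 2.
# No cross-axis misalignment terms: six positions identify exactly the six
# bias/scale parameters.

#' Estimate per-axis bias and scale from six static orientations
#'
#' @param six_series Named list of six [accel_series()] in g units, one per
#'   orientation `"+x", "-x", "+y", "-y", "+z", "-z"` (labels taken from
#'   names or from each series' `orientation` field).
#' @return A `calibration_model`: `bias` and `scale` (length-3, g and
#'   dimensionless) plus a `residual_report` data.frame giving, per
#'   orientation, the deviation of the calibrated aligned-axis gravity
#'   reading from 1 g.
#' @export
six_position_calibrate <- function(six_series) {
  labels <- names(six_series)
  if (is.null(labels) || !all(nzchar(labels))) {
    labels <- vapply(six_series, function(s) s$orientation %||% "", "")
  }
  if (!setequal(labels, SIX_ORIENTATIONS) || length(labels) != 6) {
    stop("need exactly one series per orientation ",
         paste(SIX_ORIENTATIONS, collapse = " "), "; got: ",
         paste(labels, collapse = " "), call. = FALSE)
  }
  names(six_series) <- labels
  for (s in six_series) {
    assert_series(s)
    if (s$units != "g") stop("calibration series must be in g units",
                             call. = FALSE)
    if (length(s) == 0) stop("zero-length calibration series", call. = FALSE)
  }
  means <- vapply(six_series[SIX_ORIENTATIONS],
                  function(s) colMeans(axis_matrix(s)), numeric(3))
  axes <- c("x", "y", "z")
  bias <- scale <- numeric(3)
  for (i in 1:3) {
    mp <- means[i, paste0("+", axes[i])]
    mm <- means[i, paste0("-", axes[i])]
    bias[i] <- (mp + mm) / 2
    scale[i] <- (mp - mm) / 2
  }
  if (any(scale <= 0)) {
    stop("estimated non-positive scale; check orientation labels",
         call. = FALSE)
  }
  model <- structure(list(bias = bias, scale = scale,
                          residual_report = NULL),
                     class = "calibration_model")
  resid <- vapply(SIX_ORIENTATIONS, function(lab) {
    cal <- apply_calibration(six_series[[lab]], model)
    axis <- match(substr(lab, 2, 2), axes)
    abs(abs(mean(axis_matrix(cal)[, axis])) - 1)
  }, 0)
  model$residual_report <- data.frame(orientation = SIX_ORIENTATIONS,
                                      deviation_g = unname(resid))
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model>\n")
  cat(sprintf("  bias  (g): %s\n", paste(sprintf("%+.5f", x$bias), collapse = " ")))
  cat(sprintf("  scale    : %s\n", paste(sprintf("%.5f", x$scale), collapse = " ")))
  if (!is.null(x$residual_report)) {
    cat(sprintf("  max |residual| from 1 g: %.5f g\n",
                max(x$residual_report$deviation_g)))
  }
  invisible(x)
}

#' Apply a calibration model to a raw recording
#'
#' Inverts the sensor model per axis: `a_cal = (a_raw - bias) / scale`.
#' Refuses to run twice on the same series.
#'
#' @param series An [accel_series()] in g units.
#' @param model A `calibration_model` from [six_position_calibrate()].
#' @return The calibrated [accel_series()], flagged `calibrated = TRUE`.
#' @export
apply_calibration <- function(series, model) {
  assert_series(series)
  stopifnot(inherits(model, "calibration_model"))
  if (series$units != "g") {
    stop("apply_calibration expects a series in g units", call. = FALSE)
  }
  if (isTRUE(series$calibrated)) {
    stop("calibration has already been applied to this series",
         call. = FALSE)
  }
  m <- axis_matrix(series)
  m <- sweep(sweep(m, 2, model$bias, "-"), 2, model$scale, "/")
  series <- set_axes(series, m)
  series$calibrated <- TRUE
  log_stage(series, "apply_calibration")
}

#' Dynamic validation against known single-tone trials
#'
#' Runs the spectral frequency and amplitude estimators on each trial
#' recording and tabulates per-trial percentage deviations
#' `100 * (est - true) / true` plus two aggregates: the mean absolute
#' frequency error (Hz) and the mean signed percentage frequency error.
#'
#' @param trials List of trials; each a list with `series`
#'   ([accel_series()]), `true_frequency_hz`, and optionally
#'   `true_amplitude` (peak, m/s^2).
#' @param preprocess_cfg [preprocess_config()] used before frequency
#'   estimation.
#' @return A `deviation_report`: data.frame `trials` plus aggregate fields
#'   `mean_abs_freq_error_hz` and `mean_pct_freq_error`.
#' @export
dynamic_validation <- function(trials, preprocess_cfg = preprocess_config()) {
  if (!length(trials)) stop("empty trial list", call. = FALSE)
  rows <- lapply(trials, function(tr) {
    s <- run_preprocess(tr$series, preprocess_cfg)
    sp <- compute_spectra(s)
    dom <- dominant_frequency(sp)
    f_est <- dom$dominant_frequency_hz
    f_true <- tr$true_frequency_hz
    a_true <- tr$true_amplitude %||% NA_real_
    a_est <- if (!is.na(a_true)) {
      tone_amplitude(tr$series, f_est)
    } else NA_real_
    data.frame(true_frequency_hz = f_true,
               est_frequency_hz = f_est,
               freq_deviation_pct = 100 * (f_est - f_true) / f_true,
               true_amplitude = a_true,
               est_amplitude = a_est,
               amp_deviation_pct = 100 * (a_est - a_true) / a_true)
  })
  tab <- do.call(rbind, rows)
  structure(list(trials = tab,
                 mean_abs_freq_error_hz =
                   mean(abs(tab$est_frequency_hz - tab$true_frequency_hz)),
                 mean_pct_freq_error = mean(tab$freq_deviation_pct)),
            class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf("<deviation_report> %d trials\n", nrow(x$trials)))
  cat(sprintf("  mean |freq error|: %.4f Hz\n", x$mean_abs_freq_error_hz))
  cat(sprintf("  mean signed freq error: %+.3f %%\n", x$mean_pct_freq_error))
  if (any(!is.na(x$trials$amp_deviation_pct))) {
    cat(sprintf("  max |amp deviation|: %.3f %%\n",
                max(abs(x$trials$amp_deviation_pct), na.rm = TRUE)))
  }
  invisible(x)
}
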