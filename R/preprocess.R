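# Preprocessing chain: convert units -> fill gaps -> detrend ->
# zero-phase Butterworth band-pass -> normalise (per-axis mean removal).
# The 1 Hz high-pass is the load-bearing stage: postural shifts, baseline
# drift and voluntary gross motion live below 1 Hz and would otherwise
# dominate the spectrum; tremor content of interest is 1-12 Hz.

#' Preprocessing configuration
#'
#' @param highpass_cutoff_hz High-pass cutoff (Hz), default 1.
#' @param lowpass_cutoff_hz Optional low-pass cutoff (Hz), default 15;
#'   `NULL` disables the low-pass.
#' @param filter_order Butterworth order per pass (default 4; zero-phase
#'   application doubles the effective order).
#' @param zero_phase Apply forward-backward (no phase lag); default `TRUE`.
#' @param gap_policy `"linear_interpolation"` or `"hold_last"`.
#' @param detrend `"linear"` or `"none"`.
#' @param normalize `"mean_removal"` or `"none"`.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(highpass_cutoff_hz = 1.0,
                              lowpass_cutoff_hz = 15.0,
                              filter_order = 4L,
                              zero_phase = TRUE,
                              gap_policy = c("linear_interpolation",
                                             "hold_last"),
                              detrend = c("linear", "none"),
                              normalize = c("mean_removal", "none")) {
  gap_policy <- match.arg(gap_policy)
  detrend <- match.arg(detrend)
  normalize <- match.arg(normalize)
  if (highpass_cutoff_hz <= 0) {
    stop("highpass_cutoff_hz must be > 0", call. = FALSE)
  }
  if (!is.null(lowpass_cutoff_hz) &&
      lowpass_cutoff_hz <= highpass_cutoff_hz) {
    stop("lowpass cutoff must exceed highpass cutoff", call. = FALSE)
  }
  if (filter_order < 1) stop("filter_order must be >= 1", call. = FALSE)
  structure(list(highpass_cutoff_hz = highpass_cutoff_hz,
                 lowpass_cutoff_hz = lowpass_cutoff_hz,
                 filter_order = as.integer(filter_order),
                 zero_phase = isTRUE(zero_phase),
                 gap_policy = gap_policy,
                 detrend = detrend,
                 normalize = normalize),
            class = "preprocess_config")
}

#' Fill masked gaps in a recording
#'
#' Replaces samples flagged in `gap_mask` according to the policy; the mask
#' is retained for audit and the series length never changes.
#'
#' @param series An [accel_series()].
#' @param policy `"linear_interpolation"` (default; end gaps take the
#'   nearest valid value) or `"hold_last"`.
#' @return The gap-filled [accel_series()].
#' @export
fill_gaps <- function(series, policy = c("linear_interpolation",
                                         "hold_last")) {
  assert_series(series)
  policy <- match.arg(policy)
  if (!any(series$gap_mask)) return(series)
  if (all(series$gap_mask)) {
    stop("all samples are masked; nothing to interpolate from",
         call. = FALSE)
  }
  good <- !series$gap_mask
  t <- series$timestamps
  m <- axis_matrix(series)
  for (j in 1:3) {
    if (policy == "linear_interpolation") {
      m[, j] <- stats::approx(t[good], m[good, j], xout = t,
                              rule = 2)$y
    } else {
      idx <- cummax(ifelse(good, seq_along(good), 0L))
      idx[idx == 0L] <- which(good)[1]  # leading gap: backfill first value
      m[, j] <- m[idx, j]
    }
  }
  series <- set_axes(series, m)
  log_stage(series, paste0("fill_gaps:", policy))
}

#' Remove a least-squares linear trend per axis
#'
#' @param series An [accel_series()] with at least 2 samples.
#' @return The detrended [accel_series()] (axis means ~ 0).
#' @export
detrend_series <- function(series) {
  assert_series(series)
  if (length(series) < 2) stop("need >= 2 samples to detrend", call. = FALSE)
  t <- series$timestamps - mean(series$timestamps)
  m <- axis_matrix(series)
  for (j in 1:3) {
    beta <- sum(t * (m[, j] - mean(m[, j]))) / sum(t * t)
    m[, j] <- m[, j] - mean(m[, j]) - beta * t
  }
  series <- set_axes(series, m)
  log_stage(series, "detrend")
}

#' Butterworth band-pass filter a recording
#'
#' High-pass at `highpass_cutoff_hz` plus (optionally) low-pass at
#' `lowpass_cutoff_hz`, each a Butterworth of `filter_order`, applied
#' per axis. Zero-phase by default (forward-backward with odd-reflection
#' padding), so no time shift is introduced.
#'
#' @param series An [accel_series()] with gaps already filled.
#' @param config A [preprocess_config()].
#' @return The filtered [accel_series()].
#' @export
bandpass_filter <- function(series, config = preprocess_config()) {
  assert_series(series)
  fs <- series$nominal_rate_hz
  if (!is.null(config$lowpass_cutoff_hz) &&
      config$lowpass_cutoff_hz >= fs / 2) {
    stop("lowpass cutoff must be below Nyquist", call. = FALSE)
  }
  hp <- butter_design(config$filter_order, config$highpass_cutoff_hz, fs,
                      "high")
  lp <- if (!is.null(config$lowpass_cutoff_hz)) {
    butter_design(config$filter_order, config$lowpass_cutoff_hz, fs, "low")
  }
  apply_one <- function(v) {
    if (config$zero_phase) {
      v <- filtfilt(hp$b, hp$a, v)
      if (!is.null(lp)) v <- filtfilt(lp$b, lp$a, v)
    } else {
      v <- lfilter(hp$b, hp$a, v)
      if (!is.null(lp)) v <- lfilter(lp$b, lp$a, v)
    }
    v
  }
  m <- axis_matrix(series)
  for (j in 1:3) m[, j] <- apply_one(m[, j])
  series <- set_axes(series, m)
  log_stage(series, sprintf("bandpass:%g-%s Hz order %d%s",
                            config$highpass_cutoff_hz,
                            if (is.null(config$lowpass_cutoff_hz)) "Inf"
                            else sprintf("%g", config$lowpass_cutoff_hz),
                            config$filter_order,
                            if (config$zero_phase) " zero-phase" else ""))
}

#' Run the full preprocessing chain
#'
#' Composition, in order: unit conversion to m/s^2, gap filling, linear
#' detrend, Butterworth band-pass (1-15 Hz default, zero-phase), per-axis
#' mean removal. Each applied stage is appended to the series'
#' `processing_log`.
#'
#' @param series A raw [accel_series()] (g or m/s^2).
#' @param config A [preprocess_config()].
#' @return The preprocessed [accel_series()] in m/s^2.
#' @export
run_preprocess <- function(series, config = preprocess_config()) {
  assert_series(series)
  s <- convert_units(series, "m_per_s2")
  s <- fill_gaps(s, config$gap_policy)
  if (config$detrend == "linear") s <- detrend_series(s)
  s <- bandpass_filter(s, config)
  if (config$normalize == "mean_removal") {
    m <- axis_matrix(s)
    s <- set_axes(s, sweep(m, 2, colMeans(m), "-"))
    s <- log_stage(s, "normalize:mean_removal")
  }
  s
}
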