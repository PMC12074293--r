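#' Standard gravity used for unit conversion (m/s^2 per g)
#'
#' @format A length-one numeric.
#' @export
STANDARD_GRAVITY <- 9.81

#' Construct a tri-axial acceleration recording
#'
#' `accel_series` is the container every pipeline stage consumes and returns:
#' a uniformly sampled tri-axial acceleration recording with elapsed-time
#' stamps, unit metadata, a per-sample gap mask marking missing/interpolated
#' samples, and free-text provenance.
#'
#' @param timestamps Numeric vector of seconds since recording start,
#'   strictly increasing.
#' @param x,y,z Numeric acceleration per axis, same length as `timestamps`.
#'   `NA` values are permitted only where `gap_mask` is `TRUE`.
#' @param units Either `"g"` or `"m_per_s2"`.
#' @param nominal_rate_hz Nominal sampling rate in Hz (default 55.56, the
#'   logger rate the pipeline was designed around).
#' @param gap_mask Logical vector flagging samples whose value could not be
#'   parsed or was interpolated; defaults to all `FALSE`.
#' @param provenance Free-text origin (file path, simulation seed, ...).
#'
#' @return An object of class `accel_series`.
#' @seealso [read_logger_csv()], [simulate_tremor()], [run_preprocess()]
#' @export
accel_series <- function(timestamps, x, y, z,
                         units = c("m_per_s2", "g"),
                         nominal_rate_hz = 55.56,
                         gap_mask = NULL,
                         provenance = "") {
  units <- match.arg(units)
  n <- length(timestamps)
  if (is.null(gap_mask)) gap_mask <- rep(FALSE, n)
  if (length(x) != n || length(y) != n || length(z) != n ||
      length(gap_mask) != n) {
    stop("timestamps, x, y, z and gap_mask must have equal length",
         call. = FALSE)
  }
  if (n >= 2 && any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(nominal_rate_hz) || nominal_rate_hz <= 0) {
    stop("nominal_rate_hz must be a positive number", call. = FALSE)
  }
  bad <- (is.na(x) | is.na(y) | is.na(z)) & !gap_mask
  if (any(bad)) {
    stop("NA acceleration values outside the gap mask at index ",
         which(bad)[1], call. = FALSE)
  }
  structure(
    list(timestamps = as.numeric(timestamps),
         x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
         units = units,
         nominal_rate_hz = as.numeric(nominal_rate_hz),
         gap_mask = as.logical(gap_mask),
         provenance = as.character(provenance),
         calibrated = FALSE,
         processing_log = character(0)),
    class = "accel_series"
  )
}

#' @export
length.accel_series <- function(x) length(x$timestamps)

#' @export
print.accel_series <- function(x, ...) {
  n <- length(x)
  dur <- if (n >= 2) x$timestamps[n] - x$timestamps[1] else 0
  cat(sprintf("<accel_series> %d samples, %.1f s @ %.2f Hz nominal, units=%s\n",
              n, dur, x$nominal_rate_hz, x$units))
  if (any(x$gap_mask)) cat(sprintf("  gaps: %d samples masked\n", sum(x$gap_mask)))
  if (isTRUE(x$calibrated)) cat("  calibration applied\n")
  if (length(x$processing_log)) {
    cat("  processing:", paste(x$processing_log, collapse = " -> "), "\n")
  }
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
as.data.frame.accel_series <- function(x, ...) {
  data.frame(timestamp = x$timestamps, x = x$x, y = x$y, z = x$z,
             gap = x$gap_mask)
}

axis_matrix <- function(series) {
  cbind(x = series$x, y = series$y, z = series$z)
}

set_axes <- function(series, m) {
  series$x <- m[, 1]; series$y <- m[, 2]; series$z <- m[, 3]
  series
}

log_stage <- function(series, stage) {
  series$processing_log <- c(series$processing_log, stage)
  series
}

assert_series <- function(series) {
  if (!inherits(series, "accel_series")) {
    stop("expected an `accel_series` object", call. = FALSE)
  }
  invisible(series)
}
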