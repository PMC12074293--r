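# Logger CSV dialect: optional comment lines starting with '#'
# (e.g. "# units: g"), an optional "timestamp,x,y,z" header, then one data
# line per sample: a timestamp field (numeric seconds or ISO-8601
# wall-clock) followed by >= 3 comma-separated accelerations. Extra
# trailing fields are ignored; unparseable value fields become masked gaps.

parse_timestamp <- function(s) {
  v <- suppressWarnings(as.numeric(s))
  if (!any(is.na(v))) return(v)
  t <- as.POSIXct(s, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                 "%H:%M:%OS"))
  if (any(is.na(t))) {
    stop("unparseable timestamp: ", s[which(is.na(t))[1]], call. = FALSE)
  }
  as.numeric(t)
}

#' Read a time-stamped accelerometer logger CSV
#'
#' Parses the device's SD-card log format: each data line is a timestamp
#' followed by x, y, z accelerations. Timestamps may be numeric seconds or
#' ISO-8601; they are normalised to elapsed seconds starting at 0. Lines
#' whose value fields fail numeric parsing are kept with `gap_mask = TRUE`
#' (the preprocessing gap policy fills them later), never silently dropped.
#'
#' @param path Path to the CSV file.
#' @param units Units of the stored values, `"m_per_s2"` or `"g"`. A
#'   `# units:` comment in the file takes precedence.
#' @param nominal_rate_hz Nominal sampling rate recorded in the series; if
#'   `NULL`, estimated as the median sampling interval's reciprocal.
#' @return An [accel_series()].
#' @export
read_logger_csv <- function(path, units = c("m_per_s2", "g"),
                            nominal_rate_hz = NULL) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  for (cl in grep("^#", lines, value = TRUE)) {
    m <- regmatches(cl, regexec("units\\s*[:=]\\s*(\\S+)", cl))[[1]]
    if (length(m) == 2 && m[2] %in% c("g", "m_per_s2")) units <- m[2]
  }
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) &&
      grepl("^timestamp", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1]
  }
  if (!length(lines)) stop("no data lines in ", path, call. = FALSE)
  fields <- strsplit(lines, ",", fixed = TRUE)
  ok <- vapply(fields, length, 0L) >= 4
  if (!any(ok)) stop("no parseable data lines in ", path, call. = FALSE)
  fields <- fields[ok]
  ts <- parse_timestamp(vapply(fields, `[[`, "", 1))
  if (any(diff(ts) <= 0)) {
    stop("non-monotonic timestamps in ", path, call. = FALSE)
  }
  val <- function(i) {
    suppressWarnings(as.numeric(vapply(fields, `[[`, "", i)))
  }
  x <- val(2); y <- val(3); z <- val(4)
  gap <- is.na(x) | is.na(y) | is.na(z)
  ts <- ts - ts[1]
  if (is.null(nominal_rate_hz)) {
    nominal_rate_hz <- if (length(ts) >= 2) {
      1 / stats::median(diff(ts))
    } else 55.56
  }
  accel_series(ts, x, y, z, units = units,
               nominal_rate_hz = nominal_rate_hz,
               gap_mask = gap, provenance = path)
}

#' Write an acceleration series in the logger CSV format
#'
#' Emits a `# units:` comment, a `timestamp,x,y,z` header, then one line
#' per sample with fixed 6-decimal precision (below sensor resolution, so
#' write/read round-trips are stable). Byte output is deterministic for a
#' given series. Masked samples are written as `NaN` value fields so the
#' gap survives a round-trip.
#'
#' @param series An [accel_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_logger_csv <- function(series, path) {
  assert_series(series)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("# units: %s", series$units),
               sprintf("# nominal_rate_hz: %.6f", series$nominal_rate_hz),
               "timestamp,x,y,z"), con)
  if (length(series)) {
    fmt <- function(v) {
      out <- sprintf("%.6f", v)
      out[is.na(v)] <- "NaN"
      out
    }
    writeLines(paste(sprintf("%.6f", series$timestamps),
                     fmt(series$x), fmt(series$y), fmt(series$z),
                     sep = ","), con)
  }
  invisible(path)
}

#' Convert acceleration units
#'
#' Exact linear map between g and m/s^2 using 1 g = 9.81 m/s^2.
#' Idempotent when `target_units` equals the current units.
#'
#' @param series An [accel_series()].
#' @param target_units `"m_per_s2"` or `"g"`.
#' @return The converted [accel_series()].
#' @export
convert_units <- function(series, target_units = c("m_per_s2", "g")) {
  assert_series(series)
  target_units <- match.arg(target_units)
  if (series$units == target_units) return(series)
  f <- if (target_units == "m_per_s2") STANDARD_GRAVITY else 1 / STANDARD_GRAVITY
  series <- set_axes(series, axis_matrix(series) * f)
  series$units <- target_units
  log_stage(series, paste0("convert_units:", target_units))
}

#' Load the cohort demographics and per-test result tables
#'
#' Reads the patient demographics table (one row per participant) and the
#' clinical results table (one row per patient x test, mirroring the
#' per-test summary layout: per-axis dominant frequencies, energy
#' concentration band, band-average amplitude). `NaN`/empty cells become
#' `NA`; a test row with all-missing analysis fields is marked
#' `performed = FALSE`.
#'
#' Packaged transcriptions of the study's printed tables live in
#' `system.file("extdata", ..., package = "tremoracc")`:
#' `pd_demographics.csv`, `control_demographics.csv`,
#' `clinical_test_results.csv`.
#'
#' @param patients_path CSV with columns `patient_id, age, gender,
#'   years_diagnosed, medication, dominant_hand, group`.
#' @param results_path CSV with columns `patient_id, test_id, age,
#'   years_diagnosed, dom_freq_x_hz, dom_freq_y_hz, dom_freq_z_hz,
#'   energy_band, band_avg_amplitude`. `NULL` to skip.
#' @return A list with `patients` (data.frame) and `records` (data.frame of
#'   class `cohort_table`, empty if `results_path` is `NULL`).
#' @export
load_cohort_tables <- function(patients_path, results_path = NULL) {
  req_p <- c("patient_id", "age", "gender", "years_diagnosed",
             "medication", "dominant_hand", "group")
  patients <- utils::read.csv(patients_path, stringsAsFactors = FALSE)
  miss <- setdiff(req_p, names(patients))
  if (length(miss)) {
    stop("demographics table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(patients$age < 0 | patients$age > 120)) {
    stop("implausible age in demographics table", call. = FALSE)
  }
  pd <- patients$group == "PD"
  if (any(pd & is.na(patients$years_diagnosed))) {
    stop("PD rows must carry years_diagnosed", call. = FALSE)
  }
  records <- empty_cohort_table()
  if (!is.null(results_path)) {
    req_r <- c("patient_id", "test_id", "age", "years_diagnosed",
               "dom_freq_x_hz", "dom_freq_y_hz", "dom_freq_z_hz",
               "energy_band", "band_avg_amplitude")
    raw <- utils::read.csv(results_path, stringsAsFactors = FALSE,
                           na.strings = c("NA", "NaN", ""))
    miss <- setdiff(req_r, names(raw))
    if (length(miss)) {
      stop("results table missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    if (nrow(raw)) {
      key <- paste(raw$patient_id, raw$test_id)
      if (anyDuplicated(key)) {
        stop("duplicate (patient, test) keys in results table: ",
             key[duplicated(key)][1], call. = FALSE)
      }
      raw$performed <- !is.na(raw$band_avg_amplitude)
      records <- raw[c(req_r, "performed")]
      class(records) <- c("cohort_table", "data.frame")
    }
  }
  list(patients = patients, records = records)
}

empty_cohort_table <- function() {
  df <- data.frame(patient_id = integer(0), test_id = integer(0),
                   age = numeric(0), years_diagnosed = numeric(0),
                   dom_freq_x_hz = numeric(0), dom_freq_y_hz = numeric(0),
                   dom_freq_z_hz = numeric(0), energy_band = character(0),
                   band_avg_amplitude = numeric(0), performed = logical(0))
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Path to a packaged cohort fixture
#'
#' @param name One of `"pd_demographics.csv"`, `"control_demographics.csv"`,
#'   `"clinical_test_results.csv"`.
#' @return Absolute path to the installed fixture.
#' @export
cohort_fixture <- function(name) {
  p <- system.file("extdata", name, package = "tremoracc")
  if (!nzchar(p)) stop("unknown fixture: ", name, call. = FALSE)
  p
}
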