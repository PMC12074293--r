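# Cohort summaries. Pooling unit: individual non-missing test amplitudes
# (patients x tests), not per-patient means — the only scheme that
# reproduces the printed age-group means from the per-test table. SD uses
# the sample (n - 1) denominator and is undefined (NA) for n < 2.

default_age_bins <- function() {
  list(c(60, 64), c(65, 69), c(70, 74), c(75, 79))
}

default_years_bins <- function() {
  list(c(0, 4), c(5, 8), c(9, 12))
}

pool_by_bins <- function(records, key, bins) {
  stopifnot(is.data.frame(records))
  if (!key %in% names(records)) {
    stop("records lack the grouping column: ", key, call. = FALSE)
  }
  vals <- records$band_avg_amplitude
  keys <- records[[key]]
  keep <- !is.na(vals)
  vals <- vals[keep]; keys <- keys[keep]
  assigned <- rep(FALSE, length(vals))
  rows <- lapply(bins, function(b) {
    sel <- keys >= b[1] & keys <= b[2]
    assigned <<- assigned | sel
    v <- vals[sel]
    data.frame(group = sprintf("%g-%g", b[1], b[2]),
               n_values = length(v),
               mean_amplitude = if (length(v)) mean(v) else NA_real_,
               sd_amplitude = if (length(v) >= 2) stats::sd(v) else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "unbinned") <- data.frame(value = vals[!assigned],
                                      key = keys[!assigned])
  attr(out, "n_total") <- length(vals)
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Age-stratified tremor-amplitude summary
#'
#' Pools every non-missing band-average amplitude across all tests of all
#' patients whose age falls in each bin (bins closed on both ends) and
#' reports the count, mean and sample SD per bin. Records whose age falls
#' outside every bin are collected in the `"unbinned"` attribute, never
#' silently dropped.
#'
#' @param records A `cohort_table` data.frame (see [load_cohort_tables()]
#'   or [analyze_test()]).
#' @param bins List of `c(lo, hi)` age bins; default 60-64, 65-69, 70-74,
#'   75-79.
#' @return A `group_summary` data.frame with columns `group`, `n_values`,
#'   `mean_amplitude`, `sd_amplitude`.
#' @export
aggregate_by_age <- function(records, bins = default_age_bins()) {
  pool_by_bins(records, "age", bins)
}

#' Disease-duration-stratified tremor-amplitude summary
#'
#' As [aggregate_by_age()], grouping on `years_diagnosed` instead
#' (default bins 0-4, 5-8, 9-12 years).
#'
#' @param records A `cohort_table` data.frame.
#' @param bins List of `c(lo, hi)` year bins.
#' @return A `group_summary` data.frame.
#' @export
aggregate_by_years_diagnosed <- function(records,
                                         bins = default_years_bins()) {
  pool_by_bins(records, "years_diagnosed", bins)
}

#' Compare a patient's spectral summary against a control's
#'
#' Purely descriptive: reports each side's energy-concentration band and
#' band-average amplitude, plus their ratio, for the same clinical test.
#'
#' @param patient,control `spectra` objects from [compute_spectra()] for
#'   the same test protocol.
#' @param test_id Clinical test both recordings belong to.
#' @param control_test_id Test id of the control recording if tracked
#'   separately; must equal `test_id`.
#' @return A list: `test_id`, `patient_band`, `control_band`,
#'   `patient_amplitude`, `control_amplitude`, `amplitude_ratio`
#'   (patient / control).
#' @export
compare_to_control <- function(patient, control, test_id = NA,
                               control_test_id = test_id) {
  stopifnot(inherits(patient, "spectra"), inherits(control, "spectra"))
  if (!identical(test_id, control_test_id)) {
    stop("patient and control summaries come from different tests",
         call. = FALSE)
  }
  pb <- energy_band(patient)
  cb <- energy_band(control)
  pa <- band_avg_amplitude(patient, pb)
  ca <- band_avg_amplitude(control, cb)
  list(test_id = test_id,
       patient_band = pb, control_band = cb,
       patient_amplitude = pa, control_amplitude = ca,
       amplitude_ratio = pa / ca)
}
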