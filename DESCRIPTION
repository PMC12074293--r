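Package: tremoracc
Title: Tremor Analysis for Wrist-Worn Tri-Axial Accelerometer Recordings
Version: 0.1.0
Authors@R:
    person("tremoracc", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for characterising Parkinsonian tremor
    from low-cost wearable accelerometers. Reads time-stamped CSV logger
    files, applies six-position static calibration, preprocesses recordings
    (gap filling, detrending, zero-phase Butterworth band-pass filtering,
    unit conversion), and summarises tremor by per-axis power spectral
    density: dominant frequency with parabolic peak interpolation, dominant
    axis, 2-Hz energy-concentration band, band-average amplitude and
    windowed tri-axial energy. Includes a synthetic-signal generator with
    ground truth for validation, per-test clinical result tables and
    age- and disease-duration-stratified cohort summaries, plus a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
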