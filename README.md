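# tremoracc

Quantitative tremor analysis for wrist-worn tri-axial accelerometer
recordings, aimed at movement-disorder monitoring with low-cost MEMS
sensors. The package takes a recording from raw logger CSV to a clinical
result row: six-position static calibration, preprocessing (gap filling,
detrending, zero-phase Butterworth filtering, unit conversion), per-axis
spectral characterisation, and age- / disease-duration-stratified cohort
summaries. A synthetic-signal generator with ground truth makes every
stage testable without access to clinical recordings.

## The method in brief

A recording sampled at $f_s = 55.56$ Hz is modelled per axis as gravity +
tremor tone + sub-1-Hz drift + voluntary motion + white noise. After a
zero-phase 4th-order Butterworth band-pass (1–15 Hz; the 1 Hz high-pass
removes drift and voluntary components), each axis gets a full-length
Hann periodogram. Reported per test:

* **Dominant frequency** per axis: highest PSD peak in 1–12 Hz, refined by
  parabolic interpolation on the log spectrum (sub-bin accuracy,
  ≤ 0.02 Hz mean absolute error on 60 s tones); the **dominant axis** is
  the axis with the largest peak.
* **Energy-concentration band**: the 2-Hz band [1,3), [3,5), …, [11,13)
  maximising tri-axial integrated PSD.
* **Band-average amplitude** (m/s²): mean amplitude-spectrum value over
  the in-band bins of all three axes.
* **Windowed energy**: $\sum (x^2+y^2+z^2)$ per 1 s window.

Calibration uses the six-position method: with axis readings $m^\pm$ under
±1 g, $\mathrm{bias} = (m^+ + m^-)/2$ and $\mathrm{scale} = (m^+ - m^-)/2$
per axis; recordings are corrected as $(a - \mathrm{bias})/\mathrm{scale}$.

## Worked example

```r
library(tremoracc)

# simulate a resting-test recording (seed fixes the drawn tremor frequency)
cfg <- scenario_preset(1, "mild", seed = 7)
cfg$tremor_frequency_hz
#> [1] 5.795091

s   <- simulate_tremor(cfg)                      # 3333 samples, 60 s
row <- analyze_test(s, patient_id = 1, test_id = 1,
                    meta = list(age = 65, years_diagnosed = 5))
as.data.frame(row)[, c("dom_freq_x_hz", "dom_freq_y_hz", "dom_freq_z_hz",
                       "energy_band")]
#>   dom_freq_x_hz dom_freq_y_hz dom_freq_z_hz energy_band
#> 1      5.794868      5.794843      5.794809     5.0-7.0
```

The 5.795 Hz tone is recovered on every axis to within 0.0003 Hz and lands
in the [5, 7) Hz energy band. Cohort aggregation over the packaged
per-test result table (one row per patient × clinical test; tests the
patient could not perform are missing and excluded):

```r
tabs <- load_cohort_tables(cohort_fixture("pd_demographics.csv"),
                           cohort_fixture("clinical_test_results.csv"))
aggregate_by_age(tabs$records)
#>   group n_values mean_amplitude sd_amplitude
#> 1 60-64        8       0.772875    0.2167092
#> 2 65-69       22       1.163623    0.3758597
#> 3 70-74        5       1.044880    0.2054921
#> 4 75-79       10       2.048520    2.4743491
```

Mean tremor amplitude rises with age, with the 75–79 group both strongest
and most variable (one patient contributes an 8.98 m/s² writing-test
amplitude).

## Command line

```sh
Rscript inst/cli/tremoracc simulate --preset 1 --severity mild --seed 7 --out rec.csv
Rscript inst/cli/tremoracc analyze  --in rec.csv --patient 1 --test 1 --out row.csv
Rscript inst/cli/tremoracc cohort   --patients inst/extdata/pd_demographics.csv \
        --results inst/extdata/clinical_test_results.csv --out by_age.csv
```

Subcommands: `simulate`, `calibrate`, `preprocess`, `analyze`, `cohort`,
`validate`. Every run writes a JSON manifest (config, version, input
digests, seed); identical inputs and seed give byte-identical outputs.

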