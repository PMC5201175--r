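# bst1map

Bloch-Siegert B1 mapping and B1-corrected variable flip angle (VFA) T1
relaxometry for breast MRI at 3 T, with inversion recovery (IR) as the
gold standard, plus the accuracy and test-retest reproducibility
statistics used to validate the correction. Digital phantom generators
(gel tubes, two-tissue breast) with forward signal simulation and Rician
noise let the full pipeline run without scanner data.

## What it does

VFA T1 mapping assumes the prescribed flip angles are achieved. At 3 T
the transmit (B1) field varies by tens of percent across the breast, and
fitting with the nominal angles biases the apparent T1 by roughly the
square of the local transmit scale `f`. The package:

* simulates off-resonant Bloch-Siegert pulses with a full Bloch
  integrator (`simulate_pulse_phase()`), builds phase-versus-B1 lookup
  tables (`build_lookup_table()`), and inverts measured phase-difference
  maps into per-voxel flip-angle correction maps
  (`correction_map_from_phase()`);
* fits voxelwise SPGR/VFA and magnitude-IR T1 maps with a vectorized
  Levenberg-Marquardt solver (`fit_vfa()`, `fit_ir()`), with or without
  the correction map;
* segments adipose and fibroglandular tissue from an adipose-nulled IR
  image (`segment_adipose()`, `segment_fibroglandular()`);
* computes percent error, Lin's concordance correlation, a subject-level
  bootstrap of the improvement from correction, and test-retest
  statistics (within-subject SD, repeatability coefficient `2.77 * wSD`,
  coefficient of variation) with distributional prechecks;
* wraps everything in reproducible study runners: `run_phantom_study()`,
  `run_cohort_study()`, `run_patient_study()`.

## Worked example

An eight-tube gel phantom with T1 values from 322 to 1558 ms, a
left-right transmit ramp (`f` from 0.8 to 1.1), and SNR-50 Rician noise.
The study pulse is a 2 ms Fermi pulse at 2.29 uT RMS played at +/-1500 Hz:

```r
library(bst1map)

study_pulse()
#> <pulse_spec> fermi  2 ms, 2.29 uT RMS, offset 1500 Hz, 2000 steps

build_lookup_table(study_pulse())
#> <phase_lookup> fermi_2ms_1500Hz_2.29uT  64 points over [0, 5.72] uT, phase span 0.5362 rad

res <- run_phantom_study(snr = 50, seed = 1)
tab <- dplyr::mutate(dplyr::select(res$table, tube, t1_true_ms, ir_mean_ms,
         vfa_mean_ms, vfa_b1_mean_ms, pct_err_vfa, pct_err_vfa_b1),
       dplyr::across(-tube, ~round(.x, 1)))
print.data.frame(as.data.frame(tab), row.names = FALSE)
#>    tube t1_true_ms ir_mean_ms vfa_mean_ms vfa_b1_mean_ms pct_err_vfa pct_err_vfa_b1
#>  tube_1        322      322.0       231.5          311.1        28.1            3.4
#>  tube_2        328      328.7       296.2          329.9         9.9            0.4
#>  tube_3        835      836.5       927.3          843.1        10.9            0.8
#>  tube_4        843      842.7       607.7          861.2        27.9            2.2
#>  tube_5       1004     1002.8       906.1         1015.3         9.6            1.2
#>  tube_6       1478     1474.4      1633.7         1450.7        10.8            1.6
#>  tube_7       1500     1501.4      1077.4         1539.1        28.2            2.5
#>  tube_8       1558     1561.1      1406.8         1526.6         9.9            2.2
```

Uncorrected VFA errors track the transmit ramp (10-28%); with the
Bloch-Siegert correction every tube lands within ~3% of the IR reference.
`run_cohort_study()` repeats this for a test-retest cohort of synthetic
breast phantoms and returns tidy accuracy, reproducibility, and bootstrap
tables; see `vignette("methods")` for the model equations and design
notes.

## Reproducing results

All runners are deterministic for a fixed `seed`. An end-to-end
acceptance run that writes the main computed quantities to JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

## Tests

```r
testthat::test_dir("tests/testthat", package = "bst1map",
                   load_package = "installed")
```
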