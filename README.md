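# tympanr

Signal processing, simulation and clinical metrics for smartphone-based
226 Hz probe-tone tympanometry.

Tympanometry screens middle-ear function by sweeping the air pressure in a
sealed ear canal from +200 to −400 daPa while a 226 Hz tone plays, and
recording the acoustic admittance — expressed as the volume (mL) of an
equivalent air cavity — as a function of pressure. The resulting curve, the
tympanogram, peaks near ambient pressure in a healthy ear, flattens with
middle-ear fluid or a perforation, and shifts negative with eustachian-tube
dysfunction. Commercial tympanometers are expensive; a low-cost alternative
drives a syringe plunger with a stepper motor to sweep the pressure and uses
a phone to play and record the probe tone at 24 kHz.

`tympanr` implements the complete computational chain of such a device, for
engineers and hearing-screening researchers who want to develop, test or
audit the pipeline without hardware:

* **simulator** — a physics-based forward model (isothermal gas law for the
  syringe pneumatics, first-order leaks, admittance-dependent reflected-tone
  amplitude, motor-reversal transients, Bluetooth notification jitter, clock
  offset, sensor/microphone noise) that generates complete sessions with
  known ground truth, including no-seal, occluded-tip, seal-loss and
  safety-abort scenarios;
* **seal monitor** — the acquisition state machine: a seal is declared when
  a 0.5 mm probe step raises pressure faster than 17 daPa/s (an unsealed
  probe registers ~2 daPa/s), an occluded tip when the reflected tone
  exceeds 65 dB SPL-equivalent, seal loss when pressure returns to ambient
  mid-sweep, and an abort when the plunger travels past 16 mm;
* **sync** — recovery of the true sweep boundaries from jittered
  notifications using the 220–230 Hz envelope, and an affine remap of the
  pressure clock onto the audio clock;
* **tympanogram** — per-segment single-bin 24000-point FFT magnitudes of the
  probe tone (`N` segments, one per sweep pressure sample), cubic
  calibration `p1·x³ + p2·x² + p3·x + p4` fitted on 0–5 mL hard-backed
  cavities with a slope-compensation line from the 0 mL curve, 5 daPa
  binning, window-5 moving average, and the clinical metrics (peak
  admittance, peak pressure, ear canal volume);
* **clinical** — Liden–Jerger classification (A/As/Ad/B/C, configurable
  age-banded cutoffs), Bland–Altman device agreement, curve RMSE over
  overlapping pressure ranges, percent agreement across raters.

Everything is tidyverse-shaped: traces and tympanograms are tibbles,
fitted objects have `tidy()`/`glance()` methods, results have `autoplot()`.

## Worked example

Calibrate a simulated device on its six cavity sessions, then measure a
normal (Type A) ear:

```r
library(tympanr)

cavities <- lapply(0:5, function(v)
  simulate_cavity(v, noise = noise_config(seed = v)))
cal <- calibrate_device(cavities)
cal
#> <calibration_model>
#>   cubic: -0.00516547 x^3 + 0.271882 x^2 + -5.21074 x + 35.8566
#>   slope line: m = 0.000392172 mL/daPa, b(-400) = -0.229123 mL
#>   gain_setting: 85

session <- simulate_session(ear_model("A"), noise = noise_config(seed = 42))
run_monitor(session)
#> <seal_monitor_result> outcome: sealed (2 verdicts)

res <- analyze_session(session, cal)
tidy(res)
#> # A tibble: 1 × 5
#>   peak_admittance peak_pressure ear_canal_volume is_flat peak_admittance_absolute
#>             <dbl>         <dbl>            <dbl> <lgl>                      <dbl>
#> 1           0.718            10            0.706 FALSE                       1.42

classify_tympanogram(res$metrics, age_years = 9)
#> [1] "A"
```

The simulated ear had a 0.7 mL canal volume and a 0.74 mL compensated peak
at +15 daPa; the pipeline recovers 0.706 mL, 0.718 mL and +10 daPa (one
5 daPa bin off) through the full chain — noisy audio, jittered
notifications, clock offset, calibration and smoothing. `peak_admittance`
is baseline-compensated (maximum minus the +200 daPa value);
`peak_admittance_absolute` is the raw maximum.
`plot_tympanogram(res$tympanogram, res$metrics)` draws the curve with the
peak annotated.

A shell entry point wrapping the same functions ships at `inst/cli/tympan`
(subcommands `simulate`, `battery`, `monitor`, `sync`, `calibrate`,
`analyze`, `classify`, `compare`).

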