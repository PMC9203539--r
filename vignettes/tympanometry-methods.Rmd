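---
title: "Methods: simulated tympanometry and the analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated tympanometry and the analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(tympanr)
```

# The measurement this package models

Tympanometry sweeps the air pressure in a sealed ear canal while a 226 Hz
probe tone plays, and records how easily acoustic energy flows into the
middle ear — the acoustic admittance, expressed as the volume (mL) of an
equivalent air cavity. A healthy eardrum transmits best near ambient
pressure and stiffens as pressure deviates, so the admittance-vs-pressure
curve (the tympanogram) has a peak near 0 daPa; fluid behind the eardrum
flattens it, negative middle-ear pressure shifts it left.

`tympanr` implements the computational chain of a low-cost pneumatic
tympanometer in which a stepper-driven syringe varies pressure between
+200 and -400 daPa while a phone records the reflected tone at 24 kHz:

1. **seal monitoring** — deciding from streaming pressure and audio whether
   the probe is sealed, occluded, dislodged, or the plunger has over-travelled;
2. **synchronization** — aligning the pressure-sensor clock with the audio
   clock from jittered sweep-boundary notifications;
3. **admittance extraction** — per-segment single-bin FFT magnitudes of the
   probe tone;
4. **calibration** — a cubic map from raw amplitude to mL fitted on
   hard-backed cavities of 0–5 mL, plus a slope-compensation line;
5. **smoothing and metrics** — 5 daPa binning, moving average, peak
   admittance / peak pressure / ear canal volume;
6. **classification and agreement** — Liden–Jerger classes and
   Bland–Altman statistics.

Because the package is developed without hardware, a physics-based
simulator generates complete sessions with known ground truth; every stage
is tested against it.

# The forward model

## Pneumatics

The syringe (12.5 mm plunger), tubing and the coupled ear or cavity form a
closed air volume `V0`. Advancing the plunger by `d` mm compresses it
isothermally:

$$P_\mathrm{gauge}(d) = P_\mathrm{amb}\left(\frac{V_0}{V_0 - A\,d} - 1\right),$$

with `A` the plunger cross-section (mL/mm) and ambient pressure
10132.5 daPa absolute. The default tubing-plus-probe dead volume of
9.76 mL is fixed by inverting this relation so that a full +200 to
-400 daPa sweep into a 1 mL ear displaces the plunger 5.3 mm, matching the
hardware this models. Unsealed probes leak: the gauge pressure relaxes
toward 0 with a first-order time constant. The no-seal default
(`r tympanr:::NO_SEAL_LEAK_TAU` s) was solved by root-finding so that a
0.5 mm / 1.19 s probe step registers a least-squares rate of 2.03 daPa/s —
the operating point that separates "probe in open air" (~2 daPa/s) from
"sealed" (~50 daPa/s) around the 17 daPa/s decision threshold.

```{r gas-law}
pressure_from_displacement(c(-1, 0, 0.5, 1), pneumatic_config(),
                           coupled_volume = 1)
```

## Acoustics

The reflected tone amplitude decreases with the equivalent volume `V` seen
by the probe:

$$a(V) = \frac{s}{V_c + V},$$

with scale `s = 0.476` (full-scale × mL) and coupler volume
`V_c = 7` mL (the acoustic load of probe head and tubing). Any strictly
monotone decreasing map would serve — calibration inverts it — but this
reciprocal form matches low-frequency rigid-cavity acoustics. `V_c = 7` was
chosen so that (a) a cubic polynomial inverts the map to under 0.01 mL at
the six calibration nodes, and (b) reflected levels straddle the 65 dB SPL
occlusion threshold with margin: normal ears and cavities sit at 56–63 dB
SPL-equivalent, a blocked tip (amplitude set directly to 0.5 full scale —
the volume map does not apply to a blocked port) at ~78 dB. Absolute sound
level exists only through `level_reference`: a full-scale sinusoid is
defined as 85 dB SPL, the probe's output level.

An ear is a Gaussian admittance peak on a flat baseline:

$$V(p) = v_{ec} + y_{peak}\,
  e^{-\left((p - \mathrm{tpp})/w\right)^2}.$$

Type defaults: A (0.7 mL canal volume, 0.74 mL peak at +15 daPa), As
(0.20 mL peak), Ad (1.80 mL), B (flat, 2.0 mL canal volume), C (peak at
-225 daPa). The default half-width `w = 65` daPa (~108 daPa full width,
mid-range clinically) is narrow enough that every curve genuinely flattens
at the +200 daPa anchor where ear canal volume is read.

```{r admittance}
admittance_at(ear_model("A"), c(-400, 0, 15, 200))
```

## Imperfections

`noise_config()` holds everything separating an ideal session from a
realistic one, with defaults chosen as plausible for the hardware class:

* pressure sensor noise, SD 1 daPa; microphone noise, SD 0.002 full scale
  (≈ -34 dB relative to a typical in-ear tone);
* Bluetooth notification jitter, uniform on [0, 0.2] s (up to 0.4 s in
  stress tests; always below the 0.5 s search window);
* a multiplicative amplitude drift of 5 × 10⁻⁵ per daPa below +200 (3%
  across the sweep) — the slope artifact that motivates the calibration's
  compensation line;
* a constant offset of up to ±0.2 s between the pressure clock and the
  audio clock — the desynchronization the sync stage exists to solve;
* the motor-reversal transient at each sweep turning point (next section).

`noise_preset("none")` zeroes all of these except the reversal transient,
giving byte-reproducible ideal sessions for oracle tests.

# Synchronization: why the details look the way they do

The sweep-boundary notifications arrive late by an unknown Bluetooth delay,
so the true turning instants are recovered from the audio envelope in the
500 ms before each notification: find the reversal dip, then take the
envelope maximum between the dip and the notification.

Three numerical choices make this well-posed, and all three follow from one
constraint: the analysis band is 220–230 Hz, so only amplitude modulations
slower than ~5 Hz survive filtering.

* **Frame length.** The envelope is the per-frame RMS of the band-passed
  signal. A frame of exactly two probe-tone periods (212 samples,
  ~8.85 ms) makes the RMS of the tone independent of its starting phase;
  a 10 ms frame (2.26 periods) ripples by several percent frame-to-frame,
  which is larger than the envelope curvature near a turning point and
  would make the "maximum after the dip" land frames away.
* **The reversal transient.** The transient is modeled as a smooth Hann
  dip (depth 0.5, duration 0.05 s, centred 60 ms before the reversal)
  followed by a rebound overshoot (0.4 above baseline, twice the duration,
  crest at the reversal instant). After band-filtering, the composite
  becomes a sag-then-crest whose crest stays at the reversal instant; the
  refinement rule then recovers the boundary to within one frame for
  notification delays anywhere in [0, 0.4] s, on flat (cavity, Type B) and
  peaked backgrounds alike. A rectangular dip, by contrast, is smeared
  roughly tenfold by the 10 Hz band and leaves no landmark at the turn.
* **Dip prominence.** Candidate dips must drop at least 10% of the window
  median below the envelope maximum *to their right* (their recovery
  peak). A late notification clips the dip's onset at the window's left
  edge, so a left- or two-sided prominence would starve there; the
  recovery peak is always inside the window.

The pressure record is then remapped affinely so its own maximum- and
minimum-pressure instants land on the refined boundaries — a two-point
affine map, the minimal assumption two anchors support.

```{r sync}
s <- simulate_session(ear_model("A"),
                      noise = noise_config(notify_jitter_max = 0.3, seed = 1))
sy <- synchronize(s$audio, s$pressure, s$events)
c(refined_t3 = sy$t3, true_t3 = s$truth$t3,
  refined_t5 = sy$t5, true_t5 = s$truth$t5)
```

# Admittance extraction and the sensor rate

The audio between the refined boundaries is cut into `N` equal segments —
`N` the number of pressure samples inside the sweep — and each segment,
zero-padded to 24000 samples, contributes the magnitude of the 226 Hz bin
of its FFT (1 Hz bins at 24 kHz; computed as a direct single-bin DFT,
which is identical because trailing zeros add nothing). A full-length
on-bin sinusoid of amplitude `A` yields `24000·A/2`.

The pressure sensor is simulated at 45.2 Hz — 226/5, one sample per five
tone periods. The rate is deliberately commensurate with the tone: each
audio segment then spans an integer number of tone half-periods, and the
single-bin magnitude of a sinusoid over an integer number of half-periods
carries no spectral-leakage ripple from its negative-frequency image. At
an incommensurate rate (e.g. 100 Hz, segments of 2.26 periods) that ripple
is ~7% of the amplitude, which calibration would convert into
±0.5 mL excursions — an artifact of bookkeeping, not of physics. Real
sensors are not tone-locked; on real data the equivalent remedy would be
windowing or image-corrected demodulation, at the cost of the exact
`N·A/2` bin scale.

Segments within a guard interval of the boundaries (0.05 s after the sweep
start, 0.10 s before its end — the support of the reversal transient) are
discarded; the affected edge bins are refilled by the empty-bin rule below.

# Calibration

Sessions over rigid cavities of 0, 1, …, 5 mL anchor the amplitude scale.
The amplitude "at +200 daPa" is the mean over sweep samples at 170 daPa
and above (~11 samples), which averages residual segment-level ripple; the
3% drift contributes only 0.15% across that span and is common to all six
cavities, so the cubic absorbs it. Ordinary least squares fits

$$\hat V(x) = p_1 x^3 + p_2 x^2 + p_3 x + p_4$$

through the six (amplitude, volume) pairs; monotonicity over the fitted
amplitude range is checked numerically. The calibrated 0 mL curve still
carries the drift-induced tilt; a least-squares line through it — slope
`m` (mL/daPa) and value `b` at -400 daPa, i.e. the compensation
`m·(p+400) + b` — is subtracted from all subsequent measurements. The
anchoring at -400 daPa is chosen so that subtracting the line from the
0 mL curve itself leaves only noise; the order (cubic first, then line) is
fixed so the slope is in mL/daPa.

```{r calibration}
cavities <- lapply(0:5, function(v)
  simulate_cavity(v, noise = noise_config(seed = v)))
cal <- calibrate_device(cavities)
tidy(cal)
glance(cal)
```

# Smoothing and metrics

Calibrated points are averaged into 5 daPa bins on the canonical
-400..+200 grid (121 bins); empty bins take the mean of the nearest
non-empty neighbour on each side (the single neighbour at the edges); a
centred moving average of window 5 bins (truncated at the edges) finishes
the curve. Both steps preserve constants and never widen the value range.
Calibrated output is clamped at zero, since admittance cannot be negative.

Metrics follow standard tympanometric practice: ear canal volume (ECV) is
the admittance at +200 daPa, where the eardrum is stiffened and the probe
sees essentially the canal; peak pressure is the grid pressure of the
maximum (ties broken towards 0 daPa); peak admittance is
baseline-compensated (maximum minus ECV); a compensated peak below 0.1 mL
flags the curve as flat — Type-B-like. The uncompensated maximum is also
reported (`peak_admittance_absolute`).

```{r metrics}
res <- analyze_session(simulate_session(ear_model("A"),
                                        noise = noise_config(seed = 2)), cal)
tidy(res)
```

```{r plot}
plot_tympanogram(res$tympanogram, res$metrics)
```

# Classification and agreement

Liden–Jerger classification applies a fixed rule order — B if flat, else C
if the peak pressure lies below the negative cutoff, else As/Ad if the
compensated peak falls below/above the admittance cutoffs, else A. The
shipped cutoffs (C below -100 daPa; As under 0.3 mL; Ad over 1.4 mL, all
ages) are standard literature values, not any clinic's table; the criteria
object/JSON is the interface for substituting age-banded institutional
cutoffs.

Device agreement uses Bland–Altman statistics (differences are
device2 − device1, reference first; limits are bias ± 1.96 SD), RMSE
between curves over their overlapping pressure range only, and percent
agreement of class labels per rater.

# What the simulator does and does not establish

The generator reproduces the measurement *mechanics*: gas-law pneumatics,
leaks, admittance-dependent reflection, reversal transients, notification
jitter, clock offset, sensor and microphone noise, and a smooth drift. It
does not emulate real middle ears (admittance peaks are exactly Gaussian,
with no asymmetry or notching), pediatric motion artifacts, transient
ambient noise, or transducer nonlinearity. Passing tests therefore
establish that the pipeline recovers what the model generates under
realistic noise — a necessary condition, not clinical validation. The
published clinical agreement figures (five-class agreement near 86%,
peak-admittance bias near -0.02 ± 0.14 mL) depend on 50 patient ears and
five human raters and are used here only as plausibility context, not as
reproduction targets.

## Problem sizes used in the test suite

Sessions are ~10 s at 24 kHz (≈ 220 k audio samples, ≈ 420 pressure
samples). The suite runs the five-scenario seal battery over 20 seeds, the
sync battery over 50 seeds at 0.4 s jitter, the 27-point Type A recovery
grid (ear canal volume × peak × peak pressure) at zero noise, a
6-cavity × 10-replicate calibration-quality run, and a 200-pair
Bland–Altman null check — about two minutes on one CPU in total. These
sizes were chosen so each property is exercised across its operating range
while the whole suite stays interactive.

# Known limitations

* The affine clock remap assumes no drift between the two anchors; real
  crystal drift over a 5 s sweep is far below the frame resolution, but
  longer protocols would need more anchors.
* The abort path's travel accounting uses the session's motor displacement
  record (the device knows its own motor position); the pressure-only
  fallback estimate assumes a sealed system and underestimates travel
  under partial leaks.
* `is_flat` uses a single 0.1 mL threshold; borderline shallow peaks (As
  vs B) are sensitive to it, exactly as they are for human raters.
* Calibration extrapolates the cubic outside the fitted amplitude range;
  measurements of ears larger than 5 mL equivalent volume (uncommon) are
  flagged only indirectly through the calibration-mismatch warning.
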