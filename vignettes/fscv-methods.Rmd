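---
title: "Models and methods behind the fscv pipeline"
author: "fscv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the fscv pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fscv)
```

## The measurement

Fast-scan cyclic voltammetry (FSCV) measures sub-second dopamine dynamics by
sweeping a carbon-fiber electrode with a triangular potential ramp — here
−0.4 V to +1.3 V and back at 400 V/s, an 8.5 ms sweep digitized at 1,000
points and repeated at 10 Hz, leaving a 91.5 ms hold at −0.4 V. Dopamine
oxidizes on the rising limb (near +0.6 V) and its quinone reduces on the
falling limb, producing a current signature per scan. A 16-channel
high-density carbon-fiber (HDCF) array records these signatures on 16 fibers
simultaneously; the amplifier reports current through a 200 nA/V
transimpedance gain (a 4.99 MΩ feedback resistor gives 1/R = 200.4 nA/V).

The package covers the complete analysis chain for such recordings:

1. raw binary streams (`writeRaw()`, `readRaw()`),
2. filtering (`preprocessStream()`),
3. chemometric separation of dopamine from pH and drift interferents
   (`fitPCR()`, `predictDA()`),
4. conversion to concentration via flow-cell calibration
   (`fitCalibrationCurve()`, `applyCalibration()`),
5. cross-channel quality control (`removeOutlierChannels()`),
6. stimulated-release and clearance kinetics (`quantifyKinetics()`),
7. group statistics across animals, weeks and stimulation parameters
   (`anovaTwoway()`, `mixedModelWeeks()`, `cvTable()`).

Because chronic in-vivo recordings of this kind are not publicly deposited,
a synthetic generator (`generateRecording()`, `generateCohort()`) emulates
the signal regimes with full ground truth, so every stage is testable at
desk scale.

## The raw dialect

Acquisition systems store these streams as signed 16-bit integers in
fixed-length time segments. The on-disk format here is
`ch<NN>/seg<KKK>.i16` — little-endian int16 samples, 30 s per segment —
plus a `meta.json` sidecar carrying the waveform geometry, gain, segment
length and the count-to-current scale. The scale is a convention of this
package (the hardware's ADC range is not part of the signal chain we model):
the full int16 range maps to ±2,000 nA, i.e. ±10 V at 200 nA/V, a
quantization step of ~0.061 nA — far below the noise floor of any real
recording. `writeRaw()` followed by `readRaw()` reproduces currents to
within one quantization step; values beyond ±2,000 nA clip.

Scan timestamps are derived as `scan index / repetition rate`; the hardware
provides no per-scan clock, and none is needed at a fixed 10 Hz repetition.

## Filtering

Two Butterworth IIR stages, in this order:

* **Per-scan low-pass** (4th order, 2 kHz) along the within-scan axis, whose
  sampling rate is `1,000 / 8.5 ms ≈ 117.6 kHz`. This removes
  non-biological high-frequency noise; at cutoff the gain is 1/√2 and the
  roll-off is 80 dB/decade.
* **Across-time high-pass** (2nd order, 0.01 Hz) applied to each of the
  1,000 potential steps as a time series at 10 Hz, run forward and backward
  (zero phase) so transients are not displaced in time. This stage *is* the
  background correction: the large charging current is constant scan to
  scan and is removed exactly, and slow drift falls below the 0.01 Hz
  cutoff.

A 0.01 Hz filter on a 30 s record spans only a third of a cutoff period, so
edge handling matters. Both passes use steady-state initial conditions
scaled to the first sample (a DC input maps exactly to its steady-state
response) and the zero-phase pass adds odd-reflection padding of three
filter orders per end. These are conventions; they are recorded in the
stream's provenance metadata and exercised directly by the tests (constant
streams are annihilated, a linear ramp leaks under 5% of its range, a 2 s
boxcar retains over 90% of its amplitude).

## Chemometrics

Measured voltammograms mix dopamine with pH shifts and residual drift.
Principal component regression (PCR) on a labeled training set separates
them. The canonical training set is five dopamine, three acidic-pH and two
basic-pH reference voltammograms; references are background-subtracted, so
zero analyte corresponds to the zero spectrum.

That last point drives a design decision: the decomposition is taken
**through the origin** (uncentered SVD) rather than around the training
mean. With background-subtracted references, analyte magnitude is a linear
functional of the spectrum through zero; uncentered PCR preserves that, so
the model reproduces its training labels exactly, maps the zero scan to
zero, and — when the retained components span the training space — agrees
with direct least-squares regression onto the training spectra to machine
precision. A centered variant is available (`center = TRUE`) but cannot
satisfy all three properties at once.

Components are retained by cumulative explained variance (99.5% by
default), capped at `rows − 1`. The regression target for DA rows is the
label concentration times the training electrode's sensitivity (the
through-origin slope of DA-row oxidation-peak current versus concentration),
so `predictDA()` returns DA-equivalent *current*; molar concentration comes
only from the electrode calibration factor downstream, mirroring the
physical measurement chain.

Scans carry a residual statistic Q (squared norm outside the retained
component space). Reference spectra are much cleaner than in-vivo scans, so
a threshold from training residuals alone would flag everything; the
pipeline re-estimates the threshold from each trace's pre-stimulation
baseline (`median + 5·MAD`, with a numerical floor of 10⁻⁹ of the scan
energy). Flagged scans are retained but marked; kinetics interpolates over
them when at most 20% of a trace is flagged, drops them when more is
flagged, and keeps everything (with a degradation flag) when fewer than 10
samples would survive.

## Calibration

Before implantation, each device is pulsed in a flow cell with three
boluses each of 0.5, 1, 2 and 4 µM dopamine. Each bolus is sampled at the
onset peak, just before the washout falloff, and midway between, and the
average per concentration enters a least-squares line through the origin
(zero dopamine ⇒ zero faradaic current; an intercept is optional). The
slope is the calibration factor in nA/µM, and
`concentration = current / factor`. Landmark detection (max in the first
third of the window; last sample ≥ 90% of the plateau; temporal midpoint)
is our convention — the sampling instants are standard, their detectors are
not specified anywhere.

Calibration can be per cohort-device or per channel; the synthetic truth
uses the cohort convention (factor = mean sensitivity), which is also what
makes per-channel ES DA estimates disperse with the fibers' sensitivity
spread.

## Kinetics: ES DA and Tau

Electrically stimulated dopamine release (ES DA) is defined as the peak
concentration within 10 s of stimulation onset minus the pre-stimulation
baseline. The baseline is the mean over the 2 s ending at onset (the window
length is our choice; stimulation occurs 5 s into a 30 s recording, so 2 s
is comfortably inside the stable pre-stimulation segment). A peak arriving
after the 10 s window does not count. Nonpositive differences are reported
and flagged `no_response`.

Tau, the clearance time constant, is fitted by nonlinear least squares of

$$c(t) = \mathrm{baseline} + A\,e^{-(t-t_\mathrm{peak})/\tau}$$

over the decay from the peak to the first return to 10% of ES DA above
baseline, with τ bounded to (0, 60] s. Larger τ means slower reuptake. The
single-exponential protocol and the endpoint are explicit, configurable
conventions. τ is reported in seconds — a time constant; group comparisons
are unaffected by the units convention. Starting values come from a
log-linear fit of the decay; a non-decaying segment or fewer than five
samples yields `tau = NA` with a `fit_failed` flag rather than a forced
number.

Recovery behavior, measured by the test suite: exact on noiseless
exponentials (to 10⁻⁶), and median relative error below 10% across a
τ ∈ {0.5, 1, 2, 5} s grid at SNR 10 with 10 Hz sampling.

## Channel QC

Per recording, a channel whose ES DA falls outside the mean ± 2 sample
standard deviations of all contributing channels is an outlier and is
removed. The rule is deliberately single-pass: re-running it on the kept
set can remove more channels (the tests demonstrate this), but the
operation itself never iterates. The mean and SD include the candidate
channel, and the scalar tested is the per-recording ES DA — the quantity
all downstream analysis uses.

Before outlier testing, channels without a believable response are set
aside as `below_threshold`: ES DA under 3× the baseline concentration noise
SD, or under an absolute 1 nM floor. The 3×-noise rule is a stand-in — the
functional-fiber threshold used in practice is never quantified — and both
constants are configurable.

## The synthetic generator

`generateRecording()` emulates what the pipeline must survive, not the
electrochemistry of a particular device:

* **Kinetics**: first-order release/reuptake, `dc/dt = r(t) − c/τ`, with
  `r(t)` delivering a fixed nanomolar quantum per stimulus pulse
  (30 Hz 15p, 60 Hz 30p or 60 Hz 60p trains, onset 5 s). Defaults
  (15 nM/pulse, τ = 2 s, 60 Hz 30p) give a ~400 nM ES DA transient — the
  10²–10³ nM regime of stimulated striatal recordings.
* **Voltammogram shape**: a unit-normalized DA template (oxidation peak on
  the rising limb at +0.6 V, half-amplitude reduction trough at −0.2 V on
  the falling limb) plus two distinct pH templates, all Gaussian-featured.
  Real template geometry is not published for this device class; shapes are
  parameterized and the chemometrics never assumes them.
* **Background**: a ±400 nA charging-current square profile per scan, a
  small exponential settling term (2 nA, τ = 60 s — a *stabilized*
  electrode after a cycling session, which is the only state in which
  recordings are taken), and a slow random walk (0.01 nA/scan step).
* **Heterogeneity**: per-channel sensitivities are log-normal around
  10 nA/µM with coefficient of variation 0.27 — the week-1 cross-fiber CV
  reported for chronic arrays — so pipeline ES DA estimates under a single
  cohort calibration factor disperse accordingly.
* **Noise**: additive white current noise, 0.3 nA SD per sample. After the
  2 kHz low-pass (noise bandwidth ≈ 2 kHz of a 58.8 kHz Nyquist) the
  detected-current SD at the oxidation potential sits near 0.06–0.10 nA,
  comfortably under the 0.4 nA stability criterion used to declare an
  electrode ready for recording.
* **Dropout**: listed channels carry background and noise but no analyte.

Identical seeds give byte-identical raw files. What the generator does
*not* emulate: movement and stimulation artifacts, electrode fouling,
Michaelis–Menten saturation of reuptake, pH transients coupled to
stimulation, and real voltammogram shapes. Passing tests therefore
demonstrate correctness of the *analysis* under controlled conditions, not
performance on any particular animal's data.

`generateCohort()` works one level up: it produces fiber-level ES DA / Tau
tables for a groups × weeks × parameters design directly (multiplicative
log-normal animal, fiber and observation effects; configurable group
effects, weekly sensitization slope, and below-threshold dropout), because
the statistics layer consumes exactly such tables and raw synthesis of
hundreds of recordings would add nothing but time. Defaults: 2 groups × 6
animals × 16 fibers × 4 weeks × 2 parameters, 500 nM base ES DA, +15%
sensitization per week, a 1.3× female release effect and 1.2× female τ
effect (matching the direction of reported sex differences), fiber CV 0.25
and observation CV 0.10 (combining to ≈ 0.27 within-animal).

## Statistics

The unit of analysis in the source protocols is the individual fiber, and
the package follows that for estimation; but fibers within an animal are
correlated, so for *inference about groups* the package also offers
animal-level aggregation, and its own null-calibration test uses per-animal
means — a fiber-level F-test under an animal random effect would not hold
its size.

* `anovaOneway()` / `anovaTwoway()`: standard decompositions via `aov`,
  Tukey HSD or Bonferroni/Šídák post-hocs through `emmeans`.
* Repeated measures: the split-plot path (`Error(subject/within)`) with a
  Greenhouse–Geisser correction. Epsilon is computed from the
  double-centered within-subject covariance,
  $\hat\varepsilon = \mathrm{tr}(CSC)^2 / ((k-1)\,\mathrm{tr}((CSC)^2))$,
  bounded to $[1/(k-1), 1]$; compound symmetry gives exactly 1.
* `mixedModelWeeks()`: REML `lmer` fit `y ~ group * week + (1 | fiber)`
  with Satterthwaite degrees of freedom, for the realistic case where not
  every fiber has a value at every week. On complete balanced data it
  agrees with the split-plot ANOVA F statistics to ~10⁻⁷ (the optimizer is
  run to `rhoend = 1e-10` precisely so this equivalence is numerical, not
  approximate). The GG correction is applied to the within and interaction
  terms from the observed fiber-by-week covariance.
* `cvTable()`: per animal, SD/mean over fibers; per group × week cell, mean
  ± SEM over animals. The default cohort reproduces ≈ 0.27 at week 1.

Significance is fixed at p < 0.05 throughout.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to give stable statistics: 30 s / 16-channel recordings for
dialect and stability checks, a 5 min baseline recording for the stability
bound, 4-channel clean recordings for full-chain recovery, 100 traces for
the noisy-τ grid, 50 seeds for the generator CV target, and 1,000 cohort
replicates for the type-I calibration (observed rate 0.055 at α = 0.05).
Tolerances follow the quantity: machine-precision equalities where algebra
guarantees them (PCR oracle, label reproduction), quantization steps for
the dialect, 2%/5%/10% for kinetics recovery under the corresponding noise
conditions.

Known limitations: the single-exponential τ model ignores saturating
reuptake; the Q screen assumes interferents outside the training space are
rare; the generator's sensitization is linear in week; and the statistics
layer implements the named tests, not Bayesian or permutation alternatives.
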