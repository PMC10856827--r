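---
title: "Methods: reliability of IMU-based running kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reliability of IMU-based running kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitrel)
```

## The problem

Inertial motion capture makes it possible to measure lower-extremity joint
angles during over-ground running outside the laboratory, but longitudinal
use — tracking a runner across training sessions on different days — is only
defensible if the measurement chain is reliable. Three sources of
disagreement between repeated measurements can be separated by design:

* **between-day**: the same runner, the first run of each of five testing
  days, processed with that day's first calibration;
* **within-day**: two separate runs on the same day and surface, processed
  with the same calibration trial;
* **calibration**: two copies of *the same run*, processed with two
  different sensor-to-segment calibration trials.

`gaitrel` implements the full analysis chain for such a five-day,
two-surface repeated-measures design — segmentation of continuous
recordings into gait cycles, 101-point time normalization, discrete
joint-angle feature extraction, ICC/SEM/MDC reliability estimation, and a
mixed-model analysis of between-day error sources — together with a
synthetic-cohort generator whose reliability structure is known
analytically, so every stage can be validated end to end.

## Pipeline

### Segmentation

Gait cycles are delimited by maxima of the right-foot anterior-posterior
position relative to the pelvis. A candidate boundary is a local maximum
whose height exceeds the signal minimum by a fraction
`prominence_frac = 0.1` of the signal range; candidates closer than
`min_period_s = 0.4` s (below any plausible running stride period) are
resolved in favour of the higher peak. Cycles found this way start slightly
before right-foot contact; no contact-event detection is attempted, since
acceleration-threshold methods are prone to false detections under variable
speeds and surfaces.

The first and last `n_trim = 3` cycles of each run are discarded as
acceleration/deceleration transients, which turns the default 46 strides
per simulated run into the ~40 analyzed cycles typical of a 140 m track
run. Cycles whose duration deviates from the run median by more than
3 SD *and* more than 2 samples are dropped before averaging; the 2-sample
floor exists because boundary indices are quantized to the sampling grid,
which makes noise-free stride durations alternate by one sample — a pure
3 SD rule would flag that quantization as outliers.

Each retained boundary-to-boundary window is resampled by linear
interpolation onto 101 points (percent-of-cycle 0–100, endpoints equal to
the boundary samples exactly). Linear interpolation is shape-preserving and
cannot overshoot; on an affine signal it is exact. The per-run waveform is
the pointwise mean over retained cycles, and stride frequency is the
reciprocal mean stride duration.

### Discrete features

Nine discrete variables are read off each averaged waveform: initial values
(IHF, IHA, IKF, IAD, IAI) at the 0% grid point, and peak values (PHA, PKF,
PAD, PAE) as the signed extremum over the closed stance window 0–40%
(41 grid points). Extremum directions follow ISB-style sign conventions:
peak hip adduction is a *minimum* (adduction negative), knee flexion,
ankle dorsiflexion, and eversion peaks are maxima. Peaks are taken on the
averaged waveform, not averaged over per-cycle peaks, because the averaged
waveform is the analysis object. Running speed (RS) is the timing-gate
value carried with the recording; stride frequency (SF) comes from the
segmentation.

### Reliability

For every variable × surface × comparison type, each of the five comparison
pairs (between-day: days 1–2, 2–3, 3–4, 4–5, and 5–2, the last closing the
set so that five two-measurement comparisons exist) yields an
`n × 2` matrix across participants. From its two-way ANOVA mean squares:

* `ICC(A,1) = (MSR − MSE) / (MSR + (k−1) MSE + (k/n)(MSC − MSE))` — the
  absolute-agreement single-measurement ICC; negative estimates are
  reported as computed, never truncated;
* `SEM = sqrt(MSE)`; `MDC = 1.96 · SEM · sqrt(2)`.

Aggregation across the five pairs reports the median and [min, max] ICC and
the median MDC. Categories use the conventional cut-offs (poor < 0.5,
moderate < 0.75, good < 0.9, excellent ≥ 0.9) with a conservative rule:
when the minimum ICC falls into a lower category than the median, the lower
category is reported. Participants missing either measurement of a pair are
excluded listwise from that pair only, with a log message. RS and SF are
not analyzed under the calibration comparison: re-processing the same run
cannot change the gate speed, and stride timing is identical by
construction.

### Between-day error sources

Per joint-angle variable, a difference matrix collects
|Δ angle|, |Δ RS|, |Δ SF| and the surface label for every participant ×
day-pair × surface (170 rows in the canonical design). The model

```
abs_diff_angle ~ abs_diff_speed + abs_diff_sf + surface + (1 | participant)
```

is fitted by REML via `lme4`. Intervals and p-values use the
normal-approximation Wald method: the original analysis tool's
degrees-of-freedom method is not knowable, and at 170 rows with 17 clusters
the normal approximation's anti-conservatism is mild — simulated interval
coverage at the study size is 93–97% (validated in the acceptance suite).
The marginal R² is the variance of the fixed-effect predictions over the
total modeled variance (fixed + random-intercept + residual), the standard
definition for mixed models. Surfaces are coded with the first level
(alphabetically, asphalt) as reference, so the surface coefficient is
woodchip − asphalt.

## The synthetic cohort generator

The generator emulates the canonical design — 17 runners × 5 days ×
2 surfaces × 2 analyzed runs (study labels 1 and 3) × 2 calibration copies,
46 strides per run at 240 Hz — with a strictly additive hierarchical offset
model. Each angle channel is a fixed periodic template (a low-order Fourier
series per channel, shaped to plausible running waveforms: e.g. initial
knee flexion near 7.5°, stance peak near 43°) plus offsets drawn once per
runner, per day, per run, per calibration, and per stride:

| level | default variance (deg²) | differs between |
|---|---|---|
| runner | 4.00 | everything |
| day | 0.55 | days |
| run | 0.25 | runs within a day |
| calibration | 0.20 | calibration trials within a day |
| stride | 0.40 | strides (averaged over ~40) |

Calibration offsets are drawn per runner × day × trial and shared across
surfaces and runs, mirroring the protocol in which each day's two walking
calibration trials are applied in processing to every run of that day. The
two calibration copies of a run share all stride-level data by
construction and differ only by the calibration offset.

Because offsets shift whole waveforms, they act additively and exactly on
every discrete feature, which makes the reliability structure analytic: for
a comparison pair, components shared by both measurements form the
between-subject variance and components that differ form the error
variance, so

```
true ICC = shared / (shared + differing)
```

with stride variance entering divided by the number of averaged strides.
Under the defaults this gives a true between-day ICC of 0.798, within-day
0.948, and calibration 0.960 for every variable — a regime chosen to mirror
the headline structure reported for real IMU running data: within-day
clearly above between-day, calibration error comparable to within-day
variation, and between-day absolute differences about twice the within-day
ones (the expected ratio under the defaults is
`sqrt(1.01/0.26) ≈ 1.97`). The published study quantifies the split of
runner-internal vs technical variance only loosely ("about half"), so
these component sizes are illustrative defaults, not fitted values.

Variance components are specified per *signal* (five angle channels), not
per variable: a whole-waveform offset necessarily moves the initial and
peak variable of one channel together, so the two variables extracted from
one channel share their reliability structure.

The right-foot AP-position channel is a cosine whose maxima fall exactly on
the true stride boundaries, so segmentation can be scored against ground
truth at sample resolution. Optional per-stride period jitter
(`period_jitter_frac`, default 0) multiplies each stride period by
`1 + N(0, frac²)`; the default is off so that the noise-free exactness
properties hold, and 1% jitter is switched on where segmentation
robustness is tested. Speed per run is runner speed + run-level variation
(SD 0.1 m/s) + timing-gate noise (SD 0.05 m/s); stride frequency is
runner-specific (mean 1.40 Hz, SD 0.05 Hz).

Two generator paths exist and are cross-validated against each other:
`generate_cohort()` synthesizes full waveform recordings for the
segmentation pipeline, and `simulate_feature_table()` produces the
identical offset arithmetic directly at the feature level, which makes
hundreds of replicate cohorts cheap for estimator-recovery studies.

One numerical subtlety: initial-value variables read the waveform at the
detected boundary sample, which sits up to half a sample away from the
analytic template phase. That offset depends only on the runner's stride
period, so it is constant across a runner's recordings and cancels exactly
in every comparison; it is invisible to ICCs and differences and only
shifts a runner's absolute level by well under 0.5°.

### What the generator does not emulate

Soft-tissue artefact, sensor drift, sensor-fusion errors, trunk/arm
channels, surface-dependent waveform *shape* changes, and non-additive
(shape-deforming) calibration errors are all outside the model. Passing
tests therefore demonstrate that the statistical machinery is correct under
a known additive error structure — not that real IMU data satisfy that
structure. Estimates on real recordings inherit whatever non-additive
errors the hardware and processing chain produce.

## Numerical and design choices

* **Trim rule**: the transient-exclusion rule is not specified by the
  source protocol; a symmetric trim of 3 cycles per end is simple,
  auditable, and reproduces ~40 analyzed cycles.
* **Degenerate ICC matrices** (zero total variance) are flagged and return
  `NA` rather than 0/0.
* **Negative MSE guard**: sums-of-squares subtractions are floored at 0 to
  absorb floating-point cancellation.
* **Between-day designs for other day counts** generalize to consecutive
  pairs plus a final (n, 2) closure when `n ≥ 3`; two days give the single
  pair (1, 2).
* **Within-day difference attribution**: day-pair rows of the difference
  matrix are labelled by the day pair; within-day summaries are attributed
  to the first day of each pair.
* **Planning utility**: `icc_precision()` estimates the expected 95% CI
  half-width of ICC(A,1) by simulation. At the study design (n = 17,
  k = 2, ICC 0.8) it returns ≈ 0.19–0.20, close to the ≈ 0.18 that
  closed-form sample-size formulas give for the same design; the two
  approaches agree only approximately and the simulation is the one this
  package stands behind.

## Problem sizes used in validation

The test and acceptance suites run entirely on synthetic data generated at
run time: the canonical 680-recording cohort once end to end (~15 s on one
core), 500 feature-level cohorts of 17 runners for ICC recovery, one
5000-runner cohort for asymptotic checks, 200 mixed-model replicates for
interval coverage and type-I error, and 1000 random small matrices against
a brute-force ANOVA oracle. These sizes give Monte-Carlo error comfortably
inside the asserted tolerances (e.g. SE ≈ 0.002 for the 500-cohort mean
ICC against a ±0.03 band).

## Known limitations

* The additive offset model cannot express reliability that differs
  between the initial and peak variable of the same channel.
* Wald inference is mildly anti-conservative at small cluster counts.
* The plateau case in peak detection (exactly equal consecutive samples)
  takes the first sample of the plateau; real quantized signals with long
  flat maxima would need a dedicated rule.
* MVNX (vendor) exports are not parsed; recordings must be provided in the
  documented session CSV schema.
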