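# gaitrel

Reliability analysis of wearable-IMU running kinematics: from continuous
joint-angle and foot-trajectory recordings to between-day, within-day, and
calibration test–retest reliability of discrete lower-extremity joint
angles, plus a mixed-model analysis of between-day error sources.

The package is written for movement scientists who use inertial motion
capture to measure running outside the laboratory and need to know whether
a change they observe across sessions exceeds measurement error.

## What it computes

The pipeline: segment each continuous run into gait cycles at the maxima of
the right-foot anterior–posterior position, trim acceleration/deceleration
cycles, time-normalize every cycle to 101 points, average per run, and read
off nine discrete variables — initial hip flexion (IHF), initial/peak hip
ab-/adduction (IHA, PHA), initial/peak knee flexion (IKF, PKF), initial/peak
ankle dorsiflexion (IAD, PAD), initial ankle inversion and peak ankle
eversion (IAI, PAE) — plus running speed (RS) and stride frequency (SF).

For each variable, surface, and comparison type (between-day, within-day,
calibration), reliability is estimated per comparison pair from the two-way
ANOVA of the `n subjects × 2` measurement matrix:

    ICC(A,1) = (MSR − MSE) / (MSR + (k−1)·MSE + (k/n)·(MSC − MSE))
    SEM      = √MSE
    MDC      = 1.96 · SEM · √2

and aggregated as the median [min, max] across the five pairs, with
conservative Koo–Li categories (poor < 0.5 ≤ moderate < 0.75 ≤ good < 0.9 ≤
excellent). Between-day error sources are analyzed with a random-intercept
linear mixed model per variable:

    abs_diff_angle ~ abs_diff_speed + abs_diff_sf + surface + (1 | runner)

fitted by REML (lme4) with Wald intervals and the Nakagawa-style marginal
R².

A synthetic-cohort generator with a known hierarchical variance structure
(runner / day / run / calibration / stride offsets on template waveforms)
provides analytically known true ICCs, so every stage — segmentation,
extraction, estimation — is validated against ground truth without any
data download. See `vignettes/gait-reliability-methods.Rmd` for the model
and all design choices.

## Worked example

```r
library(gaitrel)

cfg <- sim_config(seed = 1)       # 17 runners x 5 days x 2 surfaces
report <- run_pipeline(cfg)       # generate -> segment -> features -> reliability
print(report)
#> Pipeline report: 680 feature rows, 62 reliability estimates
#>   max |estimated - true| ICC: 0.135

subset(report$reliability$summary,
       variable == "IKF" & surface == "asphalt",
       c(type, icc_median, icc_min, icc_max, mdc_median, category))
#>          type icc_median icc_min icc_max mdc_median  category
#>   between_day      0.758   0.697   0.804       2.49  moderate
#>    within_day      0.950   0.929   0.954       1.40 excellent
#>   calibration      0.953   0.951   0.974       1.03 excellent
```

Reading: for this simulated cohort, initial knee flexion on asphalt shows
moderate between-day agreement (median ICC 0.76 across the five day-pairs)
but excellent within-day and calibration agreement, and a between-day
change smaller than the MDC of ~2.5° cannot be distinguished from
measurement error. Under the generator's default variance components the
analytic true ICCs are 0.798 (between-day), 0.948 (within-day), and 0.960
(calibration) — the 17-runner estimates above scatter around those values
(between-day medians range roughly 0.7–0.9 across variables and seeds),
and between-day absolute differences come out about twice the within-day
ones, matching the built-in 2:1 error structure.

The step-by-step drivers under `analysis/` (`01_simulate.R` …
`06_report.R`) run the same workflow as a narrative sequence, writing
tables under `results/`.

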