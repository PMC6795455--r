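---
title: "Methods: acoustic-emission biomarkers for knee osteoarthritis"
author: "kneeae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acoustic-emission biomarkers for knee osteoarthritis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneeae)
```

## The measurement problem

Osteoarthritic knees release transient high-frequency elastic waves —
acoustic emission (AE) — as joint surfaces articulate under load. An AE
sensor on the knee during sit-stand-sit movements records these as discrete
"hits": events where the signal amplitude exceeds an acquisition threshold
(36 dB re 1 µV throughout this package) until it stays quiet for a defined
gap. A candidate biomarker built from such recordings is only useful if it
is reproducible across the nuisance factors of a clinical workflow — sensor
re-application, measurement day, practitioner, machine — and if it relates
to disease or loading markers. This package implements both the
measurement chain (waveform → hits → movement quadrants → biomarkers) and
the evaluation chain (variance-component models, covariate association
model, trial power), with a synthetic-data generator standing in for the
non-public clinical recordings.

## Hit detection

`detect_hits()` performs sample-wise threshold crossing on the rectified
waveform. A hit opens at the first sample at or above the threshold and
closes once the signal has stayed below threshold for the hit-definition
time; sub-threshold gaps shorter than that remain inside the hit. After
closure no new hit may open during the lockout period; a burst outlasting
the lockout opens a hit at its first above-threshold sample past it. Per
hit, the peak amplitude is the maximum rectified sample over the hit window
and the average signal level (ASL) is the dB value of the mean rectified
voltage, so ASL ≤ peak by construction.

Numerical choices:

- All timing parameters are discretized to whole samples by `ceiling()`, so
  boundary decisions are exact and the detector agrees bit-for-bit with an
  independent per-sample state machine (this equivalence is tested on 200
  random waveforms).
- Default timing (`hit_timing()`): peak definition 200 µs, hit definition
  800 µs, lockout 1000 µs — conventional values for wide-band AE
  acquisition; the true acquisition-hardware values are unpublished, so
  these are declared defaults, not inferences, and are fully configurable.
- Amplitude is computed on the raw rectified signal; no software band-pass
  is applied. The acquisition frequency range (20–400 kHz wide-band vs
  20–80 kHz narrow-band) is carried as a configuration label only.
- A subtlety worth recording: "raising the threshold never decreases the
  number of hits" holds for bursts separated by more than the
  hit-definition time at every threshold, but not universally — lowering
  the threshold lengthens above-threshold runs, which can merge neighbouring
  bursts into a single hit and so *reduce* the count. The monotonicity test
  therefore uses well-separated bursts.

## Movement segmentation

The knee-angle convention is flexion-positive: seated ≈ 90°, standing ≈ 0°,
so "ascending" (standing up) means a decreasing angle. The sign convention
is a declared choice; nothing downstream depends on it beyond consistency.

`smooth_and_differentiate()` applies a zero-phase 2nd-order Butterworth
low-pass (default cutoff 2 Hz, far above the sit-stand-sit cadence) with
odd-reflection padding and baseline subtraction so the filter's zero-state
transient cannot bend the ends of the trace; velocity and acceleration are
central differences on the smoothed angle.

`detect_cycles()` seeds a cycle at a downward crossing of the 50%-of-range
level, pairs it with the next upward crossing, and extends both ends
outward while the angle keeps strictly rising (with a tiny tolerance that
treats seated plateaus as flat). On noiseless traces this recovers the
constructed cycle boundaries to within the filter's ~0.1 s smoothing bleed;
under realistic goniometer noise (0.5°) the cycle *count* stays exact while
boundaries can wander a few tenths of a second, because the angle derivative
vanishes at the true boundary and no estimator can localize it precisely
there. A downward crossing with no return is logged as an incomplete
segment, never a cycle.

`quadrant_boundaries()` splits the ascent at its maximum angular speed into
Q1 (ascending-acceleration) and Q2 (ascending-deceleration), and the
descent likewise into Q3 and Q4. On a raised-cosine cycle of duration T the
boundaries are exactly T/4 and 3T/4, which the tests assert analytically.
Ties in the speed maximum take the earliest sample. Quadrant intervals are
half-open `[t0, t1)`, so a hit exactly on a boundary is assigned
deterministically (to the later quadrant). Hits between cycles are labelled
off-cycle, excluded from quadrant analyses, and counted — the conservation
identity `Q1+Q2+Q3+Q4+off = total` is asserted across the pipeline. Only
the two recorded sets of five movements enter analyses; the practice set is
excluded by protocol.

## Biomarkers

Four candidates per recording set: the number of hits above threshold, and
the first three principal-component scores of the AE feature profile — per
quadrant, a 2D histogram of (ASL × peak amplitude). Defaults: ASL binned
over 30–90 dB and peak over 36–100 dB, 8 bins each, giving 4 × 64 = 256
cells. The published analysis states neither bin grid nor normalization, so
both are configuration, and every profile and PCA basis carries a bin-edge
fingerprint; mixing grids is refused rather than silently tolerated.
Profiles are unnormalized by default so the PC candidates carry intensity
as well as shape information; a normalized mode exists.

The PCA basis is fitted once on a developmental subset (mirroring the 5
clinically-mild + 3 clinically-severe developmental split) and frozen;
evaluation recordings are scored by projection only and never enter the
basis fit. Out-of-range amplitudes are clamped into edge bins and counted.

## Reproducibility models

Two Gaussian linear mixed models for a candidate biomarker, both estimated
by REML (via `lme4`):

- **day-one model** (day-1 data; each participant measured in separate
  sessions by each practitioner): machine fixed effects plus crossed random
  intercepts for participant and practitioner and a
  session-within-participant intercept. The residual is the between-set,
  within-session error.
- **longitudinal model** (all days): as above with a
  day-within-participant intercept replacing the session term.

Practitioner is modelled as crossed with participant (every practitioner
measures every participant on day 1), not nested. Variance components may
legitimately sit on the zero boundary; singular fits are flagged, not
raised. On a balanced design with a single machine and practitioner the
REML estimates coincide with closed-form nested-ANOVA estimators, which the
tests verify against an independent method-of-moments implementation.
Confidence intervals come from the profiled restricted likelihood
(`profile_confidence_intervals()`), truncated at 0 for SDs; when profiling
fails for a near-singular component the function substitutes a flagged
widest-bracket interval rather than failing. The covariate-adjusted
variants add KL grade, centered weight and contralateral pain as fixed
effects; the published adjustment set is unstated, so this default is
configuration.

## Association model

`forward_select()` starts from the participant-random-intercept-only model
and adds, one at a time, the candidate covariate with the smallest
likelihood-ratio p-value while that p-value is below 0.1. Selection uses
maximum likelihood (valid LRTs across fixed-effect structures); the final
model is refitted by REML — REML is stated for final models only. The
default candidate pool is KL grade, weight, contralateral knee pain, age,
sex, BMI, the three WOMAC domains and VAS pain; the published pool is not
enumerated, so this is an explicit choice. Collinear candidates are skipped
with a trace note. Complete cases only; no imputation.

KL grade is coded with successive-difference contrasts (the negative of
`MASS::contr.sdif`, so a coefficient reads `mean(KL_i) − mean(KL_{i+1})`),
making the intercept the unweighted average over KL levels; weight is
centered at the sample mean. Under this coding the intercept is "the
average number of hits across KL scores in individuals of mean weight and
no contralateral pain", and the tests assert that identity algebraically.

One behavioral note: with null covariates in the pool, forward selection at
p < 0.1 admits some noise covariate in roughly `1 − 0.9^k` of datasets —
that is the nominal behavior of the procedure, not a defect, and the tests
check the rate rather than pretending selection is oracle-exact.

## Power analysis

`simulate_trial_power()` simulates a two-arm trial whose outcome is the
participant-level mean biomarker: participant effects plus averaged
residuals, treated-arm mean reduced by a fraction, two-sided Welch t test.
With one measurement per participant this agrees with the closed-form
two-sample normal power formula within Monte-Carlo error (tested).
`required_n()` bisects over the group size with a common seed.

A notional trial powered at 80% for a 50% reduction needs only ~23
participants per group under the fitted variance components alone. A much
larger published notional figure (hundreds per group) is therefore not
derivable from those components; it must rest on unstated assumptions —
variance inflation between centres, dropout, a different analysis model.
The calculator deliberately exposes those as explicit inputs
(`trial_spec`) instead of hard-coding any path to a particular figure, and
no validation target is tied to one.

## The synthetic-data generator

`simulate_measurement_table()` draws one row per
participant × day × session × set from the same Gaussian mixed model the
evaluation stage fits: fixed effects for KL (successive-difference coding),
centered weight, contralateral pain and machine; independent Gaussian
random effects for participant, day-in-participant, session-in-participant
and practitioner; a residual per set. Defaults are the published point
estimates (intercept 160.13 hits; KL contrasts −81.77, 22.54, 38.39; weight
2.06 hits/kg; pain 57.05 hits; day-one components 82.06/46.02/6.05/18.74).
The design defaults emulate the repeated-measures protocol: 45
participants, 3 practitioners sharing day 1 (sensor re-applied between
sessions), 3 days × 3 weeks, 2 sets per session, randomization to one of 3
machines per participant for all sessions.

Where the publication states no value, defaults were chosen once as
field-plausible and are configurable: weight ~ N(82, 16) kg, age ~ N(62,
9), BMI ~ N(29, 4.5), KL mix 12:22:27:7 (the complete-data cohort
breakdown), contralateral pain Bernoulli(0.5); hit peak amplitudes
threshold + Exponential(mean 8 dB) truncated at 100 dB with ASL a uniform
5–15 dB below peak; quadrant proportions (0.4, 0.1, 0.1, 0.4), skewed to
the ascending-acceleration and descending-deceleration phases where hit
counts are consistently highest.

The response is continuous Gaussian — matching the Gaussian mixed models
fitted to hit counts downstream — with an optional rounded, zero-clipped
count mode for realism; parameter-recovery results use the continuous mode.
The raw-signal generators (`simulate_angle_trace`, `simulate_hit_stream`,
`simulate_waveform`) are deliberately simple: raised-cosine kinematics,
multinomial quadrant allocation, decaying-sinusoid bursts in Gaussian
noise. They are plumbing that makes the detector and segmenter testable
end-to-end, **not** physiological models: real AE waveforms, sensor
coupling, goniometer drift and bilateral cross-talk are all outside their
scope. Passing tests therefore demonstrate that the pipeline's inference is
correct *under its own model assumptions*; they cannot certify behavior on
real recordings.

## Validation by parameter recovery

The clinical dataset behind the published tables is not public, so the
pipeline is validated by recovery: the generator is configured with the
published estimates as truths and the fitted models must give them back.
The canonical experiments live in `recover_day_one_components()` (500
patients under the day-1 design), `recover_longitudinal_components()` (500
patients × 6 days) and `recover_association_model()` (50 replicates of
1000 participants × 2 measurements, estimates averaged over replicates).
These problem sizes were chosen so each experiment completes in minutes on
one CPU while keeping Monte-Carlo error well inside the recovery bands.
Two components are intrinsically hard at the protocol's own scale and are
treated accordingly: the practitioner SD rests on only 3 practitioner
levels, so its estimate is wide (the day-one experiment gives it a wide
recovery band; the longitudinal one does not assert it), and near-boundary
components can estimate to exactly 0, which is reported, not suppressed.

## Known limitations

- Count data are modelled as Gaussian throughout, as in the published
  analysis; a Poisson/negative-binomial variant is out of scope.
- The quadrant-boundary rule (split at the angular-speed peak) is a
  declared operationalization of "accelerating/decelerating" phases; an
  angle-midpoint alternative would shift boundaries on asymmetric cycles.
- Frequency-domain hit features, source localization and
  contralateral-knee feature profiles are not implemented.
- `required_n()` assumes the simulated power curve is monotone in n up to
  Monte-Carlo noise; use generous replicate counts near the target.
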