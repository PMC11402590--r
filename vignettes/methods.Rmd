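---
title: "Hybrid step counting from wrist accelerometry: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid step counting from wrist accelerometry: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wriststep)
```

## The measurement problem

A wrist-worn accelerometer records triaxial acceleration in gravitational
units (g) at 15–100 Hz. Steps appear as quasi-periodic impulses riding on the
1 g gravity vector, but the wrist also moves when its owner gesticulates,
types or stirs a pot, so counting every acceleration peak grossly
overestimates steps in free living. `wriststep` therefore counts peaks only
where a classifier has decided the wearer is walking, and smooths the
classifier's decisions with a hidden Markov model before counting. This
vignette documents each stage's model, its tunable parameters, and the design
decisions that were genuinely open.

## Signal conditioning

All step detection operates on a 1-D *conditioned vector magnitude*:

* `v = sqrt(x² + y² + z²) − 1` (g). The Euclidean norm is invariant to device
  orientation; subtracting 1 g removes static gravity.
* Clipping to ±2 g, **before** filtering, bounds pathological spikes; the
  stated order matters because a linear filter would otherwise smear an
  unbounded spike over its neighbourhood.
* A 4th-order low-pass Butterworth filter at 5 Hz removes content above the
  gait band. The filter is applied **forward and backward** (zero phase):
  step timestamps feed minute-level cadence, and a causal filter would shift
  every peak by the group delay. Phase handling was an open choice — a causal
  pass would match on-device implementations better — but zero phase keeps
  the detector's timestamps aligned with ground truth. Edge transients are
  suppressed by odd-reflection padding whose length (`3 · order · fs /
  cutoff` samples) lets the slowest filter pole decay to numerical noise; DC
  gain is exact to < 1e-6 and the analytic magnitude response is reproduced
  by the test suite.

Filter coefficients come from `signal::butter`; the zero-phase application is
implemented in the package so the padding behaviour is pinned.

## Walk classification

Epochs are 10 s, non-overlapping, with a trailing partial window discarded
(the classifier needs fixed-length inputs). Ground truth: an epoch is
*walking* iff at least four annotated steps fall in it; with a half-open
`[start, end)` step-to-epoch assignment.

The classifier is pluggable. The default backend is ridge-penalised logistic
regression (`glmnet`, fixed `lambda = 1e-3`) on 13 hand-crafted,
rotation-invariant features of the conditioned VM: moments and quantiles,
dominant frequency and band power in the 0.5–4 Hz gait band, spectral
entropy, the autocorrelation peak in the 0.3–1.2 s lag band (one stride),
zero-crossing rate, and the number of prominent peaks — a direct proxy for
the 4-step rule that makes the label boundary learnable. A gradient-boosted
backend (`xgboost`) is provided for the iterative-training contract: it
early-stops when validation loss has not improved for `patience_epochs = 5`
rounds and restores the best-validation state (the alternative reading,
last-before-trigger, was rejected as strictly worse and ambiguous only in
wording). Deep pretrained encoders are deliberately out of scope; the
pipeline contract is only "a walking probability per 10-s epoch".

Training protocol:

* **Grouped 80/20 split** — all epochs of a participant land on one side, so
  validation measures generalisation across people.
* **Augmentation** — each training window is rotated by a uniform random
  angle about a uniform random axis and its axes permuted uniformly (the
  distributions were unspecified and are our choice). Both are isometries, so
  VM-based features are exactly augmentation-invariant; the step exists for
  raw-signal backends and as a documented invariant.
* **Class reweighting** — weights `target / empirical` per class, normalised
  to mean 1, with a 10/90 walk/non-walk target reflecting free-living
  behaviour over 24 h. Short annotated collections over-represent walking;
  reweighting prevents the classifier from inheriting that bias.
* **Threshold** — hard labels at probability ≥ 0.5 (unspecified; 0.5 is the
  Bayes threshold for the reweighted loss).

Cross-validation uses grouped, **stratified** 10-fold assignment. Grouping
and stratification conflict (a participant's epochs cannot be split), so
stratification is resolved greedily: participants in descending epoch count
are assigned, among the folds with fewest participants, to the fold whose
walking fraction after assignment deviates least from the global fraction.
Fold sizes stay within one participant of equal by construction.

## HMM smoothing

Walking is strongly autocorrelated at the 10-s scale, and a point classifier
produces isolated flips. A two-state HMM over the *true* labels, with the
*predicted* label as the emitted symbol, is fitted by counting on the
validation set: add-one-smoothed transition bigrams (within participant
only), add-one-smoothed confusion matrix as emissions, smoothed first-label
marginal as the initial distribution. Decoding is exact Viterbi in log space
with a 1e-12 probability floor.

Design choices: hard-label emissions (a 2×2 confusion) rather than continuous
probability emissions — this matches "validation predictions vs ground-truth
labels" and keeps the decoder exactly checkable against exhaustive path
enumeration, which the acceptance suite does for every observation sequence
up to length 10; ties break toward non-walk so smoothing never fabricates
walking on indifferent evidence; decoding restarts at nonwear gaps, never
bridging them.

## Step detection and tuning

Peaks of the conditioned VM are counted with three heuristics: topographic
prominence ≥ `prominence_g`, width at half prominence within a bound, and a
minimum inter-peak `distance_s` enforced greedily (tallest peak wins a
conflict; equal heights prefer the earlier peak). Two open readings were
resolved explicitly:

* **Width** is an *upper* bound by default (a maximum width), with a
  `width_mode = "min"` switch, since common library defaults treat a scalar
  width as a minimum. Walking impulses are narrow; a maximum width rejects
  slow swells.
* **Runs, not epochs**: detection operates on each maximal run of consecutive
  walking epochs concatenated, so a step straddling an epoch boundary is not
  lost; a `per_epoch = TRUE` mode reproduces windowed counting (the two
  differ by at most one step per boundary, which the tests check).

Tuning is an exhaustive grid search minimising the validation mean absolute
step-count error. The grid spans prominence 0.1–1 g (step 0.1), distance
0.2–2 s (step 0.2), width 0.01 then 0.1–1 s (step 0.1) — the endpoints are
the method's stated ranges; the step sizes are ours (1100 cells, cheap
because peak candidates are parameter-independent and computed once per
signal). Ties break toward the most conservative cell (largest prominence,
then distance, then width), biasing against fabricated steps.

## Daily summaries

Steps are binned into half-open minute slots on a day grid anchored at local
midnight (timestamps are plain seconds; time zones are out of scope).
Nonwear is a stationary episode of ≥ 60 min in which every axis has a rolling
within-minute SD < 13 mg — the criterion follows standard accelerometer
processing practice, since the method itself only names the exclusion.
Nonwear minutes are imputed with the mean of the same minute-of-day on all
days where it was worn (slots worn nowhere become 0, with a warning). The
median daily step count is the median over valid days — any day with at least
one worn minute, a configurable choice the method leaves open — of the
imputed day totals; the 1-min peak cadence is the mean over days of each
day's maximum minute. QC flags: wear < 72 h (72.0 passes), any hour of day
with no worn minute on any day, mean gravity-removed acceleration > 100 mg
(100 passes); a calibration flag slot exists but is never set here, as
calibration is an external preprocessing step.

## The synthetic generator

The simulator is the package's test bed, not a biomechanical model. A walking
bout draws inter-step intervals `60/cadence · (1 + jitter · z)`, adds one
half-sine impulse (amplitude `step_impulse_g`, width ≤ 0.3 s) per step on the
body vertical axis plus an arm-swing sinusoid at half the step frequency,
adds gravity, applies an arbitrary fixed orientation, and adds Gaussian
sensor noise. Defaults — cadence 110 steps/min, jitter CV 0.05, impulse
0.5 g, swing ratio 0.3, noise 30 mg — are typical of adult free-living gait
and fixed once. Sedentary bouts carry 20 mg noise (above the 13 mg
stationarity threshold, so sitting still stays "worn"); fidget bouts add
sparse 15–35 mg transients constructed to stay below the detector's 0.1 g
prominence floor; nonwear is exactly constant gravity. Cohort presets mirror
the shapes this pipeline is meant for: ~1 h mixed free living at 25 Hz, three
lab sessions of regular/semiregular/irregular walking at 15 Hz (~37 min), and
multi-day wear with a 2-h nonwear gap whose minutes always have imputation
donors on other days. All randomness flows from one master seed through a
stable per-participant hash, so fixtures regenerate byte-identically.

What the simulator does **not** emulate: non-gait rhythmic arm motion
(typing, tooth-brushing), running or stairs, soft-tissue resonance, device
calibration error, sampling dropouts. Passing the end-to-end tests therefore
shows the pipeline's machinery is correct and self-consistent — it does not
certify accuracy on real wrist data, where epoch classification is the hard
part and a stronger backend (the pluggable interface exists for this) would
be needed.

## Numerical choices and degenerate inputs

* Probability floors: 1e-12 in all HMM log computations.
* Feature extraction maps all-constant windows to zero spectral/temporal
  features (power below 1e-12 counts as degenerate).
* Sample rate is inferred as `1/median(diff(time))`; a declared rate wins on
  a > 1% conflict, with a warning.
* Resampling is per-axis linear interpolation — the resampling scheme of the
  upstream tooling is not documented, and linear is monotone and adequate at
  gait frequencies; it is isolated in `resample_recording` so alternatives
  can be swapped.
* Zero-true-count subjects are excluded from percent-error metrics with a
  warning; metrics with zero denominators report `NA`, never a silent 0.
* Bland–Altman uses the plain 1.96 multiplier, no small-sample correction.

## Problem sizes used in the tests

The test suite and the acceptance script run on deliberately desk-scale
problems chosen as representative rather than exhaustive: 10 simulated
participants (~1 h each at 25 Hz, 3600 epochs) for the cross-validated
end-to-end check, 3 simulated days at 15 Hz for the daily-summary pipeline,
200 random plus 20 structured signals for peak-detector/oracle equivalence,
and all 2^T observation sequences with T ≤ 10 for Viterbi/enumeration
equivalence. On these conditions the pipeline recovers per-participant step
counts within a few percent and near-perfect epoch classification; the
acceptance script prints the exact numbers.

## Known limitations

* The default logistic backend is linear in 13 features; real free-living
  data will need a stronger backend through the same interface.
* Hard-label HMM emissions discard the classifier's confidence.
* The nonwear criterion and the valid-day rule are standard-practice
  defaults, not validated choices.
* Device calibration (gain/offset to local gravity) is assumed done upstream.
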