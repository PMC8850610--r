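---
title: "Connectivity neurofeedback scoring and group analysis: models and design choices"
author: "fcnef package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity neurofeedback scoring and group analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcnef)
```

## The paradigm this package computes

Functional connectivity neurofeedback (FCNef) trains participants to change
the correlation between two brain regions' BOLD signals. The paradigm
implemented here targets the connectivity between the left dorsolateral
prefrontal cortex (DLPFC, Executive Control network) and the left
precuneus/posterior cingulate cortex (PCC, Default Mode network). In healthy
people these regions are *anticorrelated*; in melancholic depression the
anticorrelation weakens. Training rewards participants for making the
correlation more negative.

The computation has five stages, each a module of this package:

1. **Session timing** (`trial_schedule`, `segment_session`): a session is
   150 s of rest followed by six trials (14 s fixation, 42 s "plus" period,
   feedback). The first 40 s of the plus period are the *induction period*;
   its first 2 s are discarded for the hemodynamic delay, so 38 s of data
   enter each trial's connectivity estimate. The first 10 volumes of the
   session are discarded for steady-state magnetisation.
2. **Preprocessing** (`build_nuisance`, `regress_out`, `bandpass`,
   `compute_fd`, `scrub`): nuisance regression on the six rigid-body motion
   parameters, the whole-brain (global), CSF and grey-matter mean signals,
   and the backward-difference derivatives of all nine; framewise
   displacement (FD) by Power's formula with a 50 mm head radius; volumes
   with FD > 0.5 mm become unit spike regressors online and are censored
   offline; a zero-phase second-order Butterworth band-pass (0.008–0.3 Hz
   online, 0.008–0.1 Hz offline).
3. **Trial scoring** (`trial_fc`, `compute_baseline`, `score_trial`,
   `sham_score`): each trial's Pearson correlation is referenced to a
   baseline estimated from a SHAM day on which feedback was random draws
   from Normal(50, 30.3). Per-trial correlations from the SHAM day are
   Fisher-transformed (z = atanh r); their mean and sample SD define the
   baseline and the score anchors.
4. **Localizer** (`build_design_matrix`, `fit_glm`, `t_contrast`,
   `peak_within_mask`, `make_sphere_roi`): the ROIs are 8 mm spheres around
   each participant's peak activation from an n-back block design — the
   2-back > rest contrast for the DLPFC and rest > 1-back + 2-back for the
   PCC — thresholded at p < 0.05 family-wise error with a 10-voxel minimum
   cluster size.
5. **Group analysis** (`resting_fc`, `change_scores`, `fit_change_model`,
   `likelihood_ratio_test`, `loo_predict`,
   `repeated_measures_task_model`): symptom change scores (later day minus
   Day 0) are modelled on resting-state connectivity change, with a 2-SD
   outlier rule, likelihood-ratio comparison of nested models, and
   leave-one-out prediction as the overfitting check.

## The score map

The feedback score is anchored at three points: 50 when a trial's
correlation equals the baseline, 100 at baseline minus one standard
deviation or lower, 0 at baseline plus one standard deviation or higher.
Only the anchors are prescribed; how to interpolate between them is a
design choice. We interpolate **linearly in Fisher-z space**,

$$\mathrm{score}(r) \;=\; \mathrm{clamp}_{[0,100]}\!\left(50 - 50\,
\frac{\operatorname{atanh} r - \bar z}{s_z}\right),$$

because the baseline statistics themselves are computed in z space, so the
score is then an affine function of the quantity whose sampling
distribution is approximately normal. The alternative reading — mean, SD
and anchors on the correlation scale — is available via
`compute_baseline(..., anchor_space = "r")`; the two agree exactly at the
three anchors and differ only in between. Scores are kept at floating
precision (no rounding is prescribed). SHAM draws are recorded both raw and
clamped to [0, 100] for display, so the generating Normal(50, 30.3)
parameters remain recoverable from the record.

```{r anchors}
baseline <- compute_baseline(c(0.3, -0.3, 0.1, -0.1))
score_trial(c(baseline$lower_anchor_r, baseline$mean_r,
              baseline$upper_anchor_r), baseline)
```

## Preprocessing choices

* **Butterworth order and application.** Only the filter family and pass
  bands are prescribed. We use order 2 applied forward–backward
  (`signal::filtfilt`), giving zero phase distortion at an effective
  fourth-order roll-off; the series is demeaned first to limit edge
  transients. On a 0.05 Hz probe sinusoid the 0.008–0.1 Hz band retains
  amplitude within 5%; a 0.2 Hz probe is attenuated below 30%.
* **FD formula.** Power-style: the sum of absolute backward differences of
  the translations plus the rotations converted to arc length on a 50 mm
  sphere, with FD fixed at 0 for the first frame.
* **Derivatives.** Backward differences with a leading 0 (whether the
  published "derivatives" were differences or spline derivatives is not
  stated; differences are the field's convention).
* **Order of operations.** Regression precedes filtering (the order the
  methods are described in); offline, censoring happens between them, so
  the filter runs on the concatenated surviving frames.
* **Intercept.** Regression always includes an intercept even though it is
  not listed among the regressors; without one, residuals retain the signal
  mean and every downstream correlation would be distorted.
* **Rank deficiency.** A rank-deficient nuisance design triggers a warning
  and a pivoted least-squares fit; residuals remain orthogonal to the
  retained column space.

## Localizer choices

* **FWE correction** is Bonferroni over in-mask voxels. The published
  threshold says only "FWE corrected"; random-field theory is out of scope,
  and on the small synthetic grids used here Bonferroni is both simple and
  conservative.
* **Cluster connectivity** is 18-neighbour (faces + edges); the minimum
  surviving cluster size defaults to 10 voxels.
* **Ties** in peak t values break toward the lowest linear voxel index in
  scan order, making the peak deterministic.
* **Orthogonalization.** Condition regressors are *not* orthogonalized by
  default; `build_design_matrix(..., orthogonalize = TRUE)` applies
  sequential orthogonalization in the order the conditions are given (the
  published design orthogonalized conditions without stating an order).
* The 3-back condition is excluded from both contrasts (participants
  disengaged from it), so it is simply not passed to `conditions`.

## The synthetic-data generator

No imaging or questionnaire data are deposited, so the package generates
every input it needs. The generator is first-class, tested code; its
defaults are the study conditions.

* **ROI pair.** Two unit-variance Gaussian AR(1) processes whose
  innovations are correlated at `target_r` via the Cholesky factor of the
  2×2 target correlation; with a common AR coefficient the stationary
  cross-correlation equals `target_r`. The AR coefficient defaults to 0.3,
  a typical BOLD lag-1 autocorrelation at TR 1 s. The Pearson/Fisher
  machinery downstream assumes approximately Gaussian signals, which this
  construction supplies.
* **Nuisance structure.** Global, CSF and grey-matter mean signals are
  smooth AR(1) series added to both ROIs with configurable amplitudes.
  Scanner drift (linear + slow sine) lives *inside the global signal* and
  reaches the ROIs through the global amplitude: drift is physically a
  whole-brain effect, and this placement is what lets global-signal
  regression remove it, exactly as the real pipeline assumes. An early
  draft added drift directly to each ROI, where only the band-pass could
  attenuate it; the residual shared variance biased the offline
  connectivity estimate by about +0.03, which is visible at the precision
  of the recovery tests.
* **Motion.** A tiny random-walk jitter (0.01 mm / 1e-4 rad steps) plus
  sustained 0.6 mm translation steps at the requested spike frames, so FD
  exceeds 0.5 mm at exactly those frames. Note a consequence verified in
  the tests: artifacts that are *linear in the motion parameters* are
  removed by nuisance regression itself (the derivative of a step is a
  spike regressor), so the demonstrable benefit of censoring comes from
  artifact shapes outside that span.
* **Localizer runs.** Spherical blobs respond to chosen conditions with a
  canonical double-gamma HRF; blob amplitude falls off as a Gaussian from
  the blob center so the planted center is the unique maximum and peak
  recovery is well-posed. Voxels outside blobs are unit white noise.
* **Cohorts.** Each participant's BDI change is
  `intercept + beta * fc_change (+ experiment shift) + noise`. Defaults: 19
  participants split 9/10 across two experiments; Day-0 connectivity near
  0.01 (the subclinical group's starting point between the healthy −0.07
  and depressed +0.09 reference values); connectivity changes
  Normal(−0.07, 0.15); slope 20 BDI points per unit connectivity change
  with residual SD 3 and intercept −2, which yields change-score
  correlations around 0.7–0.8, the regime the paradigm operates in. The
  other scales (RRS factors, STAI2) receive realistic levels with changes
  unrelated to connectivity, mirroring their role as related/unrelated
  symptom controls.

What the generator does **not** emulate: physiological (cardiac or
respiratory) noise, spatial autocorrelation of volumetric noise,
scanner-specific artifacts, non-Gaussian BOLD features, or any coupling
between head motion and the ROI signals beyond the planted artifacts.
Passing recovery tests therefore show that the estimators are correct under
their own assumptions, not that those assumptions hold in any given real
data set.

## Session timing inference

The published session length is 512 s (512 volumes at TR 1 s), composed of
150 s rest plus six trials of 14 s + 42 s plus a feedback display whose
duration is not printed. The remaining 26 s, spread over six trials
(26/6 s each), is the package's default feedback duration — an inference
that closes the accounting, not a published value. Durations that are not
whole multiples of the TR are floored to whole volumes, so partial-period
volumes are never included in any window. Windows are stored 1-based
inclusive, the R convention.

## Group-model choices

* With one change score per participant there is no replicated grouping,
  so the published mixed-effects formulation reduces to an ordinary linear
  model; the package fits `lm` there and reserves the random intercept for
  genuinely repeated measures (`repeated_measures_task_model`, task scores
  over four training days).
* Likelihoods entering likelihood-ratio tests and AIC are maximum
  likelihood (REML is never used where models are compared). The published
  AIC pairs are internally consistent with this convention:
  chi-square = AIC(reduced) − AIC(full) + 2·df reproduces the printed
  χ²(2) = 3.90 from 74.61 and 74.70.
* The 2-SD outlier rule is a single pass: mean and SD are computed once
  over all values, candidate included, and values beyond k·SD are dropped.
  It is applied per-analysis to the outcome change scores.
* Two-sided tests throughout; no multiple-testing correction is applied
  (none is prescribed).
* The leave-one-out analysis refits the change model n times, predicts
  each held-out participant from their connectivity change, and reports
  the Pearson correlation of actual versus predicted changes.

```{r group-demo}
sim <- simulate_cohort(cohort_spec(seed = 42))
cs <- change_scores(sim$cohort)
fit <- fit_change_model(cs, "BDI")
coef(fit)
loo_predict(cs, "BDI")
```

## Numerical notes and degenerate inputs

* `fisher_z` rejects |r| ≥ 1; `trial_fc` rejects zero-variance induction
  windows; `compute_baseline` rejects fewer than two trials or zero
  variance (a degenerate baseline has no score map).
* `scrub` errors when no frame survives; `resting_fc` requires at least 3
  surviving volumes.
* Scores are clamped to [0, 100] outside the anchors, so the map is total
  and monotonically nonincreasing in r.
* Gaussian smoothing uses a separable kernel truncated at ±4σ with
  symmetric boundary reflection; a flat field is exactly invariant and
  total mass is preserved within 1%.
* All generators take an explicit seed, restore the caller's RNG state,
  and are bit-reproducible per seed.

## Problem sizes used in the checks

The test suite exercises the estimators at the study's own scales: 512-
and 590-volume sessions, 38-volume trial windows, 19-participant cohorts
(larger, 40–200, where a sampling distribution is the question), 100 seeds
for recovery averages, 1000 seeds for calibration of the F test and the
likelihood-ratio null, and 10^6 draws for the SHAM generator's parameters.
The calibration of the likelihood-ratio statistic against chi-square(2) is
run at cohort size 200 because the statistic's finite-sample (Bartlett)
inflation at small n is a property of the test itself, not of this
implementation.

## Known limitations

* The package consumes realigned data plus motion parameters; realignment,
  slice-timing correction and spatial normalization are upstream and out
  of scope, as are DICOM/BIDS handling and anatomical-atlas deformation.
* The published cash-bonus mapping from scores is unspecified and not
  implemented.
* Real-time scanner integration is out of scope; "online" here means the
  per-trial computation order, not a TCP loop.
* Participant-level published statistics (e.g. the r = 0.78 BDI
  correlation) depend on raw data available only on request and are not
  reproduced; the package instead demonstrates the full chain on synthetic
  cohorts with known ground truth.
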