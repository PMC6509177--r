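---
title: "Quantifying elbow spasticity from wearable EMG and gyroscope recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying elbow spasticity from wearable EMG and gyroscope recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Spasticity is a velocity-dependent increase in muscle resistance to passive
stretch after a central nervous system lesion. Clinically it is graded on the
modified Ashworth scale (MAS), an ordinal judgement made by a therapist while
stretching the limb by hand. `spastr` implements a quantitative alternative
built on two wearable sensors: one surface-EMG channel over the biceps or
triceps (1 kHz) and one wrist-worn 3-axis gyroscope (100 Hz per axis),
recorded while an examiner performs 15-20 passive elbow stretches at varied,
hand-chosen speeds.

Two models convert a session of stretches into biomarkers:

* **Lambda model (neurogenic component).** Each trial with an evoked EMG
  burst yields a *dynamic stretch reflex threshold* (DSRT): the angle
  traversed from movement onset until the burst, obtained by integrating the
  angular speed. Regressing DSRT on mean stretch speed and extrapolating to
  zero velocity gives the *tonic stretch reflex threshold* (TSRT), the
  session's biomarker. Subjects whose trials mostly lack evoked EMG — the
  expected healthy pattern — are assigned the fallback TSRT of 120 degrees,
  the guaranteed minimum range of motion under the inclusion criteria.
* **Kinematic model (mechanical component).** Each 1-2 s stretch is compared
  with the *intended* motion under a constant-jerk assumption: a
  piecewise-linear ("subtriangular") acceleration rising to
  `acc1 = 4000` deg/s² over the accelerating phase and dipping to
  `-acc2 = -acc1·t1/t2` over the decelerating phase, so the net velocity
  change is zero. Double integration and range-of-motion scaling give a
  reference angle curve; differentiating it once and twice gives mutually
  consistent reference speed and acceleration. The biomarkers are the three
  Pearson correlations between actual and reference curves plus the median
  frequency (MDF) of the actual angular acceleration.

Three supervised calibrations map biomarkers to a continuous MAS-scale score
(grades encoded 0, 1, 1.5, 2, 3): linear regression on the TSRT alone,
multivariate linear regression on the four kinematic biomarkers, and
ε-insensitive support vector regression (SVR, RBF kernel) on the fused
five-dimensional feature vector. Leave-one-out cross-validation scores every
subject with a model trained on the others; the mean squared error against
the numeric MAS summarizes each method.

## What the synthetic cohort emulates

No recordings ship with the package; `simulate_cohort()` generates sessions
with exactly the statistical structure the two models assume, so the whole
chain is testable end to end.

* **Motion.** Each stretch follows a constant-jerk speed profile (peak
  velocity 60-270 deg/s across a session, range of motion 120-140 degrees,
  accelerating fraction 0.42-0.58), embedded in a 3-7 s trial with 1 s of
  rest before movement. Severity enters as band-limited (2-15 Hz) zero-mean
  Gaussian fluctuations added to the acceleration, with amplitude
  proportional to a per-subject `perturb_gain`, then integrated — this both
  lowers the actual-versus-reference correlations and raises the
  acceleration MDF as severity grows, the sign pattern the biomarkers rely
  on. The gyroscope reports the speed along a fixed sensor axis plus 0.1
  deg/s white noise per axis (a consumer-IMU noise floor).
* **EMG.** Gaussian baseline noise (8 µV) plus, when the traversed angle
  crosses `DSRT(v) = tsrt_true + dsrt_slope · v`, an amplitude-modulated
  20-450 Hz burst with a 50 ms rise — chosen so the burst survives the
  band-pass filter and the 3×SD envelope rule. Grade-0 subjects fire only
  above an unreachable velocity threshold; spastic subjects skip a trial's
  burst with probability 0.05 (trials without an evoked response occur in
  practice but their rate is not well characterized, so this is a free
  parameter of the simulator).
* **Grade-conditional parameters.** TSRT means 120/55/48/40/25 degrees for
  grades 0/1/1+/2/3 (SD 6, grade 0 exact), DSRT slope
  `-U(0.4, 0.7) · tsrt/135` deg per deg/s (keeps thresholds positive across
  the velocity range and matches the magnitude of published per-subject
  fits), perturbation gains 0.03/0.10/0.14/0.20/0.30 (log-normal, σ_log
  0.2). These were fixed once, before any evaluation: on the default
  24-subject tally (8×0, 4×1, 6×1+, 4×2, 2×3) they reproduce the published
  landscape closely — TSRT-MAS correlation ≈ −0.93, lambda LOOCV MSE ≈
  0.14, kinematic ≈ 0.3, biomarker-grade correlation signs (−, −, −, +).

What the simulator does **not** contain: torque or muscle mechanics, the
return half of each stretch, electrode artifacts (motion artifact, ECG
crosstalk), or between-session electrode variation. Passing tests therefore
show that the estimators recover the quantities the models define, under the
models' own assumptions — not that the models describe real muscle.

## Numerical and design choices

* **Filters.** Zero-phase (forward-backward) Butterworth designs: 4th-order
  20-450 Hz band-pass for EMG, 2nd-order 10 Hz low-pass per gyroscope axis.
  Edges are handled by odd reflection padding of three filter lengths before
  the forward-backward pass.
* **Onset detection.** The detection signal (50 ms moving-RMS envelope for
  EMG; angular-speed magnitude for movement) is compared against
  `baseline mean + 3 SD` over the first 0.5 s; the earliest run of at least
  25 ms (EMG) or 0.3 s (speed — movement lasts ≥ 0.9 s, and short
  supra-threshold noise runs should not pre-trigger) declares onset, with
  the offset at the end of that run. An optional outward refinement to the
  mean + 1 SD crossing exists but is off by default: measured on noise-free
  profiles it recovers part of the sub-threshold tails of slow stretches but
  over-extends fast ones, because the 10 Hz low-pass smears the sharp
  deceleration edge.
* **Mean stretch speed** is the average speed over the detected movement
  window. Amplitude thresholding cannot see sub-threshold motion tails, so
  this overestimates the programmed mean by a small systematic amount
  (≈ +1-4%, worst on slow stretches); the TSRT is insensitive to such a
  multiplicative velocity bias — it rescales the regression slope while
  leaving the intercept unchanged — which is why no correction is applied.
* **Outlier exclusion** in the lambda fit takes the "95% interval" as the
  95% *prediction* interval for individual observations under the initial
  OLS fit, applied once (flag, refit once, no iteration). A single pass
  matches the one-shot before/after refit the method describes, and avoids
  the instability of iterated deletion on 15-point fits.
* **Fallback boundary.** The regression path is taken only when the fraction
  of QC-passed trials with an EMG onset *strictly exceeds* 0.5; a session
  with onsets in exactly half its trials falls back to TSRT = 120. (The
  convention matters only at the exact boundary; it is configurable.)
* **Automated QC** replaces visual screening with fixed rules: no movement
  bounds; stretch duration outside 0.3-10 s; raw-EMG baseline SD above 0.5
  mV (saturation); or ≥ 5% of samples at or beyond 2.4 mV (clipping).
* **DSRT convention.** DSRT is the *traversed* angle from movement onset,
  not an absolute elbow angle — consistent with the 120-degree fallback
  equalling the guaranteed minimum range of motion. Flexor and extensor
  sessions are processed identically after the speed magnitude is formed.
* **Reconstruction discretization.** The subtriangular acceleration is
  sampled on the trial's 100 Hz grid; because the triangle vertices fall
  between samples, the decelerating lobe is rescaled once so the discrete
  trapezoidal integral is exactly zero. The reported `acc2` stays
  `acc1·t1/t2` exactly. A single angle-level scale matches the range of
  motion; reference speed and acceleration are derived from the *scaled*
  angle by central differences so the three reference curves stay mutually
  consistent.
* **MDF** is read off the raw one-sided periodogram of the mean-detrended
  acceleration over the stretch window only, DC excluded, with linear
  interpolation between bins.
* **MSE** is the mean of *squared* score-label differences. (The method's
  printed formula omits the square; the quantity is named "mean square
  error" and is implemented as such.)

## The SVR kernel width

The published constants are C = 30, ε = 0.09 and a kernel "width" of 0.007.
Under the kernel as printed, `exp(-‖d‖²/(2σ²))`, σ = 0.007 collapses the
Gram matrix to the identity for any realistic feature scale (TSRT differs
between subjects by tens of degrees), so that cannot be what was computed.
The common library convention `exp(-γ‖d‖²)` with γ = 0.007 on the raw
feature scale, however, yields a well-behaved kernel dominated by TSRT
distance and modulated by the kinematic biomarkers. The pipeline therefore
uses the identical kernel expressed in this package's convention,
`σ = 1/√(2·0.007) ≈ 8.45`, on unstandardized features. `svr_config()` itself
defaults to the constants exactly as printed, and per-fit z-scoring (with a
width suited to z-scored features, e.g. `σ = √(p/2)`) is available as a
configuration switch; when used inside cross-validation the standardization
statistics come from the training fold only.

A consequence worth knowing: with C = 30 and ε = 0.09 the SVR nearly
interpolates its 23 training subjects. On repeated synthetic cohorts the
fused model matches the lambda model's error in the median (both ≈ 0.15) and
sometimes halves it, but in a minority of replicates a held-out subject at
the edge of the feature cloud is scored by a ringing RBF expansion and the
fused MSE exceeds the lambda MSE. The single-dataset superiority of the
fused method does not, under these hyperparameters, replicate as a uniform
ordering across synthetic draws; the test suite measures and reports exactly
this.

## Problem sizes

The test suite and acceptance script run entirely on simulated data: single
sessions of 6-20 trials for unit checks, twenty 24-subject cohorts (the
published grade tally) for the replication properties, and one 24-subject
cohort for the acceptance report. These sizes keep every property estimate
stable at a few minutes of total compute on one core.

## A worked session

```{r, eval = FALSE}
library(spastr)

cohort <- simulate_cohort(master_seed = 1)
features <- extract_features(cohort)
head(features)

svr <- svr_config(sigma = 1 / sqrt(2 * 0.007))  # published kernel, raw scale
ev <- loocv(features, svr = svr)
ev
glance(ev)
autoplot(ev)

# one subject's lambda model
pts <- preprocess_session(cohort$trials[[10]])
fit <- extract_tsrt(pts)
glance(fit)
autoplot(fit)
```

## Known limitations

* The synthetic generator is the only data source; its grade-conditional
  parameter distributions are plausible but not fitted to recordings.
* The TSRT fallback makes all healthy subjects identical in the lambda
  feature, which the linear calibration exploits; cohorts without healthy
  controls will behave differently.
* Scores are deliberately unclipped and can leave [0, 3] for extreme
  feature vectors.
* The kinematic biomarkers assume a single dominant speed maximum per
  stretch; double-peaked stretches split at the earliest maximum.
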