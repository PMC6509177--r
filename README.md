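# spastr

Quantitative assessment of elbow muscle spasticity from two wearable
sensors: one surface-EMG channel over the stretched muscle (1 kHz) and one
wrist-worn 3-axis gyroscope (100 Hz), recorded while an examiner performs
15–20 passive stretches at varied speeds. The package is aimed at
rehabilitation researchers and biosignal engineers who want an objective,
continuous counterpart to the modified Ashworth scale (MAS), and at method
developers who need a fully synthetic, seeded test bed for stretch-reflex
analysis pipelines.

## The models

**Lambda model (neurogenic component).** For every trial with an evoked EMG
burst, the dynamic stretch reflex threshold is the angle traversed up to the
burst,

&nbsp;&nbsp;&nbsp;&nbsp;DSRT = ∫ ω(t) dt over [movement onset, EMG onset],

with ω the angular-speed magnitude. Per subject, an ordinary least-squares
line DSRT = slope·v̄ + TSRT is fitted against the mean stretch speed v̄, with
one-shot exclusion of points outside the 95% prediction interval. The
intercept — the tonic stretch reflex threshold (TSRT) — is the biomarker;
sessions whose trials mostly lack evoked EMG (the healthy pattern) are
assigned TSRT = 120°.

**Kinematic model (mechanical component).** Each 1–2 s stretch is compared
with its intended constant-jerk motion: a subtriangular acceleration rising
to acc1 = 4000 °/s² over the accelerating phase t1 and dipping to
−acc2 = −acc1·t1/t2 over the decelerating phase t2 (zero net velocity),
double-integrated and scaled to the actual range of motion. Biomarkers: the
Pearson correlations of actual vs reconstructed angle, speed and
acceleration, and the median frequency of the actual acceleration.

**Calibration.** MAS grades {0, 1, 1+, 2, 3} are encoded {0, 1, 1.5, 2, 3}
and predicted by (i) linear regression on TSRT, (ii) multivariate linear
regression on the four kinematic biomarkers, and (iii) ε-SVR (RBF kernel,
C = 30, ε = 0.09) on the fused 5-D feature vector. Leave-one-out
cross-validation scores every subject with a model trained on the rest; the
mean squared error (MSE) against the numeric MAS summarizes each method.

## A worked example

```r
library(spastr)

cohort   <- simulate_cohort(master_seed = 1)   # 24 subjects, published tally
features <- extract_features(cohort)
ev       <- loocv(features, svr = svr_config(sigma = 1 / sqrt(2 * 0.007)))
ev
#> <spastr_eval> leave-one-out evaluation
#>   fusion    MSE = 1.0694  (n = 24)
#>   kinematic MSE = 0.4296  (n = 24)
#>   lambda    MSE = 0.1452  (n = 24)

cor(features$tsrt, features$label)
#> [1] -0.9269719
```

The lambda method misjudges each subject by about ±0.38 MAS points on
average (MSE 0.145), with the TSRT biomarker strongly anticorrelated with
the clinical grade (r ≈ −0.93). The kinematic method is noisier (MSE ≈ 0.4).
The fused SVR matches the lambda model on most cohorts (median MSE ≈ 0.15
across seeds) but — as the seed-1 run above shows — can be destabilized by a
held-out subject at the edge of the feature cloud, because C = 30 with
ε = 0.09 leaves the 23-point expansion nearly interpolating. The methods
vignette discusses this trade-off and every other numerical choice.

One subject's lambda fit:

```r
pts <- preprocess_session(cohort$trials[[10]])
glance(extract_tsrt(pts))   # subject 10, clinical grade 1
#> # A tibble: 1 x 5
#>    tsrt  slope    r2 n_points fallback_used
#>   <dbl>  <dbl> <dbl>    <int> <lgl>
#> 1  52.2 -0.234 0.861       17 FALSE
autoplot(extract_tsrt(pts))   # DSRT vs speed with the excluded outliers
```

Sessions can be written to and re-read from a plain-CSV directory layout
(`write_cohort()` / `read_cohort()`; one folder per subject with a
`manifest.json` plus `emg_<id>.csv` and `gyro_<id>.csv`), and a thin CLI over
the same functions lives at `inst/cli/spastr`
(`simulate` / `extract` / `crossval` / `report`).

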