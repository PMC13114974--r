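# scfavolt

Quantification of fecal short-chain fatty acids (SCFAs) — propionate,
butyrate, and total SCFAs, with acetate as a mass-balance residual — from
voltammetric fingerprints, using chemometric neural-network calibration.

## The problem

Acetate, propionate and butyrate dominate the gut-microbial SCFA pool
(molar ratio roughly 60:25:15) and are routinely quantified by GC–MS, which
is accurate but slow and instrument-bound. An electrochemical alternative
records differential pulse voltammetry (DPV) and cyclic voltammetry (CV)
fingerprints of chemically pretreated fecal samples on disposable gold
electrodes: an acid-catalysed esterification route read by DPV (propionate
and total-SCFA fingerprints) and an alkaline dissociation route read by CV
(butyrate fingerprint). In standard mixtures, single descriptors extracted
from these fingerprints calibrate linearly against concentration; in real
fecal matrices, sample-dependent distortions (gain, drift, potential shift,
saturation) break any single-feature calibration, so concentrations must be
decoupled from *multi-feature* fingerprint vectors by nonlinear regression.

## What the package implements

- **Trace I/O and validation** (`voltammogram()`, `read_voltammogram()`,
  `split_cv_sweeps()`): potential/current tables in mV and uA with strict
  per-technique monotonicity checks.
- **Descriptor operators** (`baseline_correct()`, `area_in_window()`,
  `current_at()`, `potential_at_current()`, `peak_in_window()`,
  `half_wave_area()`): chord-baseline windowed areas (uA·mV),
  characteristic currents and potentials.
- **Route extractors** producing the field's named descriptors —
  propionate B\_I1/B\_I2, B\_V1/B\_V2, B\_A1/B\_A2 (currents at −30 mV,
  potentials at 1000 uA, areas over −230…−30 mV); butyrate C\_I1 (CV
  current at 175 mV), C\_I2 (reduction peak), C\_V1 (potential at 10 uA),
  C\_A1 (area over 500…110 mV, reverse sweep); total-SCFA A\_I1/A\_V1
  (peak in −200…100 mV), A\_A1 (left half-wave area), A\_I2 (current at
  985 mV), A\_A2 (area over 800…985 mV).
- **Models**: a from-scratch single-hidden-layer MLP (ReLU, Huber loss,
  Adam/Nadam, min–max input scaling fitted on training rows only). The
  propionate/butyrate network takes the 10-feature *cross-information*
  vector (six propionate-route + four butyrate-route descriptors) and
  predicts both acids simultaneously; the total-SCFA network takes the five
  total-route descriptors plus the predicted propionate (P1) and butyrate
  (B1) as auxiliary inputs (*hierarchical* design, 7 features). Acetate is
  reported as the exact residual `total − propionate − butyrate`.
  MLR (`train_mlr()`) and random-forest (`train_rf()`) baselines share the
  same feature interface.
- **Method-agreement suite** (`eval_report()` and friends): MAE/RMSE/R²,
  agreement rates within ±5 %/±10 %, Bland–Altman bias and limits of
  agreement, bootstrap CIs, paired t/Wilcoxon tests, five-fold CV with
  leakage-free per-fold scaling, Pearson feature screening.
- **In-study fixtures**: the 30-sample GC–MS vs ANN comparison cohort and
  the standard-mixture calibration anchors (mean ± SD, n = 3), packaged as
  plain CSVs.
- **Synthetic data generator** (`generate_standard_trace()`,
  `apply_matrix_effect()`, `generate_cohort()`, `build_dataset()`):
  seeded voltammograms whose extracted descriptors land exactly on the
  anchor-interpolated calibration lines, plus a configurable fecal-matrix
  distortion model — so the whole pipeline is testable without instrument
  data.

## Worked example

```r
library(scfavolt)

## agreement of the packaged 30-sample cohort with the GC-MS reference
t2 <- load_table2()
eval_report(t2$ann_total, t2$gc_total, reps = 2000, seed = 42)
#> <eval_report> n=30  MAE 0.1353  RMSE 0.2013  R2 0.9968
#>   within_5pct: 27/30 (90.0%)
#>   within_10pct: 30/30 (100.0%)
#>   bias 0.003333 mM, LoA [-0.398, 0.4047]; p(t)=0.93, p(Wilcoxon)=0.632

## seeded synthetic study: matrix distortion breaks the linear model
cfg  <- synth_config(seed = 1)
ds   <- build_dataset("pb", cfg)                      # 72 train / 30 test
ann  <- train_pb_model(ds$train, reduced_mlp_config(seed = 101), n_ensemble = 3)
mlr  <- train_mlr(ds$train, pb_feature_names(), c("ref_prop", "ref_but"))
mae(predict(ann, ds$test)[, "propionate"], ds$test$propionate_mM)
#> [1] 0.3081231
mae(predict(mlr, ds$test)[, "ref_prop"], ds$test$propionate_mM)
#> [1] 0.7047948
```

The first block reproduces the cohort's printed agreement statistics from
the packaged fixture (total-SCFA MAE 0.135 mM, RMSE 0.201 mM, 27/30 within
±5 %). The second block shows the core scientific claim on synthetic data:
under default fecal-matrix distortion the 10-feature network roughly halves
the multiple-linear-regression test error.

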