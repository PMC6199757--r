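# octgeostat

Geostatistical texture analysis of SD-OCT retinal layer maps for
computer-aided diagnosis of age-related macular degeneration (AMD).

Drusen — deposits between the retinal pigment epithelium (RPE) and Bruch's
membrane (BM) — locally lift the RPE border and change the *spatial
texture* of the RPE-drusen-complex thickness map before they change its
average. This package, aimed at medical-image-analysis researchers working
with segmented SD-OCT volumes, turns expert boundary surfaces (ILM, RPE
border, BM) into:

1. **topographic thickness maps** — total retina `TR = BM − ILM`,
   neurosensory retina `NSR = RPE − ILM`, RPE-drusen complex
   `RPEDC = BM − RPE` — plus an **en-face reflectance projection** along
   the RPE border (mean over ±d voxels axially);
2. **directional geostatistical descriptors** on a fovea-centred region of
   interest: the empirical semivariogram and semimadogram

   γ(h) = Σ (xᵢ − xⱼ)² / (2 N(h)),  m(h) = Σ |xᵢ − xⱼ| / (2 N(h)),

   over unordered pixel pairs admitted per direction (0°, 45°, 90°, 135°)
   and lag (1–15) under a ±3 lag tolerance, 10° angular half-tolerance and
   3 px bandwidth — concatenated direction-major into 60-feature vectors;
3. **SVM classification with repeated stratified k-fold evaluation**,
   reporting sensitivity, specificity, accuracy, rank-based AUROC and
   Cohen's kappa, with per-fold z-score standardization fitted on training
   splits only.

A synthetic cohort generator (foveal pit, smooth correlated layer fields,
drusen as Gaussian RPE-border elevations, speckled reflectance volumes)
makes the whole pipeline runnable and testable without clinical data.

## Worked example

```r
library(octgeostat)

params  <- synthetic_params()                      # 200 x 50 x 128 voxel eyes
cohort  <- gen_cohort(params, n_amd = 20, n_control = 20, seed = 42)
features <- extract_cohort_features(cohort,
                                    arrangement = c("RPEDC-SV", "TR-SV"),
                                    roi_radius_mm = 3)
eval_rpedc <- svm_repeated_cv(subset(features, arrangement == "RPEDC-SV"),
                              k = 5, repetitions = 10, seed = 1)
eval_rpedc
#> SVM evaluation: 5-fold x 10 repetitions, 40 cases (20 AMD / 20 other)
#>               Sens(%)  Spec(%)   Acc(%)    AUROC    Kappa
#>   Average        90.0    100.0     95.0    0.995    0.900
#>   Std             0.0      0.0      0.0    0.000    0.000
#>   Max acc        90.0    100.0     95.0    0.995    0.900
#>   Max kappa      90.0    100.0     95.0    0.995    0.900
```

The RPEDC semivariogram features separate drusen-bearing from control eyes
almost perfectly (mean AUROC 0.995): drusen inject localized variance into
the RPEDC map, which the variogram picks up across lags. The same
evaluation on total-retina features gives mean AUROC 0.608 — drusen move
the RPE border, not the retina's outer envelope, so `TR` texture carries
almost no class signal. The four table rows are the per-repetition mean,
its standard deviation, and the metrics of the best-accuracy and
best-kappa repetitions.

A shell front end mirrors the same pipeline
(`inst/cli/octgeostat simulate | features | evaluate`; exit codes 0/2/3
for success, usage error, data error).

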