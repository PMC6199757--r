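---
title: "Geostatistical texture of retinal layer maps: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geostatistical texture of retinal layer maps: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octgeostat)
```

## The problem and the model

Age-related macular degeneration (AMD) deposits drusen between the retinal
pigment epithelium (RPE) and Bruch's membrane (BM). On spectral-domain OCT
the drusen locally lift the RPE border, so the thickness of the RPE-drusen
complex (RPEDC) develops focal bumps: its *spatial texture* changes even
where its average thickness barely moves. This package classifies eyes by
describing that texture with two classical geostatistical summaries and
feeding them to a support vector machine.

The inputs are three expert-segmented boundary surfaces over the lateral
A-scan x B-scan grid: the inner limiting membrane (ILM), the RPE border and
BM, with axial depth increasing into the eye. Three topographic maps follow
by voxel subtraction:

* total retina `TR = BM - ILM`,
* neurosensory retina `NSR = RPE - ILM`,
* RPE-drusen complex `RPEDC = BM - RPE`,

so `TR = NSR + RPEDC` pixelwise (exact on integer voxel counts). A fourth,
complementary representation samples the reflectance volume along the RPE
border: the en-face projection averages intensities over an axial window of
`±d` voxels around the rounded border depth.

For a masked 2-D map the directional empirical semivariogram and
semimadogram at lag \(h\) are

\[
\gamma(h) = \frac{1}{2N(h)} \sum_{(i,j)\,:\,h_{ij}\approx h} (x_i - x_j)^2,
\qquad
m(h) = \frac{1}{2N(h)} \sum_{(i,j)\,:\,h_{ij}\approx h} |x_i - x_j|,
\]

where the sum runs over unordered pixel pairs admitted by a direction/lag
tolerance geometry and \(N(h)\) is their count. Both are nonnegative,
vanish on constant maps, scale as \(c^2\) and \(|c|\) under value scaling,
and ignore constant shifts. For i.i.d. pixels with variance
\(\sigma^2\) the semivariogram expectation is \(\sigma^2\) at every lag,
and for centred Gaussians the semimadogram expectation is
\(\sigma/\sqrt{\pi}\) — the closed forms the acceptance tests check.

## Pair-selection geometry

A pair with integer lateral offset \(v=(dx,dy)\) counts toward direction
\(\theta\) and lag \(h\) when (all intervals closed, Euclidean distances):

* \(\max(1, h-\Delta h) \le |v| \le h+\Delta h\) with lag tolerance
  \(\Delta h = 3\) by default — the lower clamp keeps the self-pair out;
* the angle between \(v\) and the \(\theta\)-axis (mod 180°) is at most the
  angular tolerance, read as a **half-angle** (default 10°, the
  geostatistics convention; with directions every 45° the sectors do not
  overlap);
* the perpendicular offset from the axis is at most the bandwidth
  (default 3 px).

Defaults: lags 1–15, directions 0°, 45°, 90°, 135°. With unit lag spacing
and \(\Delta h = 3\) the distance annuli of neighbouring lags overlap, so
adjacent-lag features are correlated by construction; that is deliberate
and kept. Offsets are canonicalized to a half-plane so each unordered pair
is counted once, which also makes \(\theta\) and \(\theta+180^\circ\)
identical, as the symmetric estimators require. The efficient path
precomputes the admissible offset set per (direction, lag) and accumulates
shifted-grid differences under the joint mask — algebraically the same
pairs as a direct loop, and `brute_force_curve()` (an \(O(P^2)\)
enumeration with per-pair tests) is kept as an independent oracle that the
test suite compares against exactly.

Distances are measured in raw pixel units on the native anisotropic grid
by default, since no physical-unit correction is part of the method
definition; `units = "PHYSICAL"` instead rescales offsets by the mm
spacing (normalized to the finer pitch) for users who want isotropic
geometry on 1000 x 100-style grids. Cells that end up with no admissible
pair keep a flagged value of 0 so feature vectors stay fixed-length under
aggressive ROIs; `strict = TRUE` turns that into an error.

## Feature vectors and evaluation protocol

Per case and arrangement (map x function; eight in total) the curve is
flattened direction-major (0°, 45°, 90°, 135°), lag-ascending — 60
features under the defaults. Concatenation rather than direction-averaging
was chosen because it preserves anisotropy, which is exactly what the
per-direction curves display. No normalization happens at extraction time;
standardization is a classifier concern and must be fitted inside each
training fold to avoid test-set leakage.

`svm_repeated_cv()` draws, per repetition, a fresh *stratified* k-fold
split (stratification prevents class-absent folds in unbalanced cohorts);
per fold it z-scores features with training-split statistics only, fits an
RBF-kernel SVM (`cost = 1`, `gamma = 1/p` — conventional defaults, exposed
in the protocol record), and scores the held-out fold with continuous
decision values. The out-of-fold predictions of a repetition are pooled
into one confusion matrix, one rank-based (Mann–Whitney, ties one half)
AUROC and one Cohen's kappa; pooling is well defined for AUROC on small
folds, where per-fold averaging is not. Aggregates report mean, SD and the
best-accuracy / best-kappa repetitions. With `k = 5` each test fold holds
20% of cases (±1), and a fixed seed reproduces the report bit for bit.

## The synthetic cohort generator

`gen_case()` builds the ILM as a base plane plus a Gaussian foveal pit and
smooth noise, stacks NSR and RPEDC thickness fields on top, and — for AMD
eyes — subtracts \(K \sim \max(1, \mathrm{Poisson}(8))\) lateral Gaussian
bumps from the RPE border (BM stays fixed), thickening the RPEDC exactly
the way drusen do. Surface noise is white noise smoothed with a Gaussian
kernel (0.2 mm default) so thickness maps carry realistic spatial
correlation for variogram testing; the noise field is generated with a
margin and cropped, keeping its variance stationary up to the scan edge.
`gen_volume()` adds a piecewise-constant reflectance profile (vitreous 30,
NSR 90, RPEDC 160, below BM 50, arbitrary units, RPEDC brightest) under
multiplicative Gamma speckle with a configurable coefficient of variation.

Default study conditions, chosen once: a 200 x 50 x 128 voxel grid
spanning 6.7 mm x 6.7 mm (the full-size 1000 x 512 x 100 geometry is
supported but needless for testing); NSR 40 ± 2 voxels, RPEDC 8 ± 1
voxels, pit 15 voxels deep with 0.5 mm width; drusen amplitudes 5–20
voxels with 0.05–0.15 mm lateral sigma, about 8 per AMD eye — amplitudes
sized so that drusen of clinical scale (≥ 125 µm laterally, tens of µm
high) remain well inside the NSR thickness, keeping boundary order valid
without clipping in practice. Cohorts of 60 + 60 cases, features under the
default geostatistical geometry, and 5-fold x 10-repetition evaluation are
the sizes used throughout the tests and the acceptance script.

What the generator emulates: focal RPEDC thickening, smooth correlated
baselines, class overlap through noise. What it does not: real speckle
physics, vessel shadows, geographic atrophy, segmentation error. Passing
tests therefore demonstrate that the *method* recovers a drusen-like
texture signal by construction — not that the headline numbers on clinical
cohorts are reproduced here. On the synthetic conditions the arrangements
order themselves as on real eyes: RPEDC semivariogram best, total-retina
and en-face arrangements near chance (the synthetic TR is genuinely
uninformative because drusen move only the RPE border, and the en-face
band reflectance is class-blind by construction).

## Numerical choices, open decisions, limitations

* **ROI radius is a required argument.** The method's region of interest
  is an anatomical cylinder around the fovea, but a 5 mm radius exceeds
  the 3.35 mm half-field of the stated scan geometry — plausibly a
  diameter. Rather than guessing, `apply_roi()` takes the radius
  explicitly; tests and the acceptance script use 3 mm, which keeps the
  disc inside the field. The disc is enforced in physical mm, hence an
  ellipse in anisotropic pixel indices.
* **En-face half-window `d` is required** for the same reason: no value is
  part of the method definition; 2 voxels is used throughout this package.
  Boundary depths are rounded half-to-even before windowing because the
  projection indexes voxels, not interpolated samples; windows clip (and
  shrink the mean) at volume edges, with a strict flag to mask instead.
* **Thickness stays in voxel units** end to end; a µm display conversion
  would touch features only as a global scale, which both estimators pass
  through transparently anyway.
* **No resampling** of the native lateral grid: interpolation would
  manufacture data, and the estimators handle anisotropic grids as-is.
* **Degenerate inputs**: boundary-order violations raise with the
  offending pixel count (an explicit `repair` flag clamps the RPE border
  and counts the repairs); undefined metrics (zero denominators,
  single-class AUROC) return `NA` with a warning, never a silent 0.
* **Limitations**: the SVM hyperparameters are fixed rather than tuned;
  variogram model fitting (sill/range/nugget) is out of scope — the raw
  curve values are the features; and the synthetic generator is a
  morphology emulator, not an optical simulator.
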