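# drsprobe

Tracking an optical-biopsy probe in video and classifying its spectra.

Diffuse reflectance spectroscopy (DRS) probes measure the broadband light
diffusely reflected by tissue at a single contact point; the spectral shape
separates tumor from normal tissue. To make those point measurements usable
during *ex vivo* specimen scanning, the probe tip must be localized in the
camera view at every frame and each acquired spectrum scored on the spot,
building up an annotated registry of "optical biopsy" sites. `drsprobe` is an
offline, fully testable implementation of that pipeline for R:

* **Synthetic generators** — scenes (a marker-banded cylindrical probe moving
  over tissue-colored background, with exact tip ground truth, occlusion and
  illumination controls) and two-class reflectance spectra (with dark/white
  references and injected no-contact outliers), so every downstream stage is
  testable without clinical data.
* **Camera calibration** — closed-form planar (checkerboard) calibration:
  homographies by normalized DLT, intrinsics `K` from the absolute-conic
  constraints, per-view `R`, `t`; the pixel→mm scale at a working distance
  `d` is `10·d_cm / f_px` (0.2804 mm/px at f = 1070 px and 30 cm).
* **Marker detection** — resize to 640×480, Gaussian blur, HSV thresholding
  (green 90–150° or cyan 160–200°), morphological opening, largest contour,
  Hough-transform edge lines, and the probe midline `y = mx + b` as their
  bisector.
* **Tip tracking** — 1-D tip search along the midline with a configurable
  end rule (yaw assumed within 0–180°), then a constant-velocity Kalman
  filter (Joseph-form updates, two-point velocity initialization, coasting
  through up to 15 missed frames).
* **Spectral preprocessing** — reference normalization
  `(raw − dark)/(white − dark)`, Savitzky–Golay smoothing (window 11,
  order 3), resampling to the 468–720 nm / 0.5 nm analysis grid (505
  points), robust MAD-based outlier removal, per-site averaging of 20
  replicates.
* **Classification** — repeated stratified cross-validation (5 folds × 5
  repeats, sites as the CV unit), per-fold z-scoring and t-statistic feature
  selection, four classifier families (exact gradient-boosted trees with
  shrinkage 0.3 / depth 6, histogram leaf-wise boosted trees, MLP, RBF SVM),
  metrics as mean ± sd of accuracy, sensitivity, specificity and AUC, and
  single-spectrum tumor probabilities for the live overlay (green = normal
  → pink = tumor).
* **Session orchestration** — streaming track + trigger-driven biopsy-site
  registry with ferrule-sized footprints (3.175 mm), persistent overlays,
  bit-reproducible archives, and tracking-error evaluation against one or
  two sets of manually labeled tip positions (per-axis RMSE/max/min in px
  and mm).

## Worked example

```r
library(drsprobe)

## Track a 120-frame synthetic scene and score the result against its truth
scene <- scene_config(
  trajectory = linear_trajectory(120, from = c(120, 290), to = c(420, 400),
                                 yaw_deg = 60),
  seed = 42
)
res <- track_scene(scene)
evaluate_tracking(
  res$track,
  data.frame(frame = res$truth$frame, x = res$truth$x, y = res$truth$y),
  mm_per_px = scene$mm_per_px
)
#> <tracking_error_report>
#>   x: RMSE 0.44 px (0.12 mm), max 0.64 px, min 0.19 px over 120 frames
#>   y: RMSE 0.67 px (0.19 mm), max 1.01 px, min 0.19 px over 120 frames

## Simulate an acquisition, preprocess it, and cross-validate a classifier
sim <- simulate_spectra(spectra_sim_config(n_sites_per_class = 20,
                                           outlier_fraction = 0.05, seed = 42))
ds  <- process_spectra(sim, tissue = "stomach")
ds
#> <spectra_dataset: 40 sites x 505 wavelengths (20 normal / 20), stomach>
run_cv(ds, classifier_spec("xgb"), make_cv_plan(ds$labels, seed = 42))
#> <evaluation_report: xgb, 5 folds x 5 repeats>
#>   accuracy      97.50 +/- 5.10
#>   sensitivity   95.00 +/- 10.21
#>   specificity  100.00 +/- 0.00
#>   auc           97.50 +/- 5.10
```

The tracking report says the estimated tip stayed within a pixel of the
commanded trajectory on both axes (about 0.1–0.2 mm at the default
0.28 mm/px scale). The cross-validation report aggregates 25 test folds;
with the default class separation and 3% noise the boosted-tree classifier
recovers the simulated tumor/normal labels almost perfectly, and the ± terms
are the fold-to-fold standard deviations.

A thin command-line front end over the same functions is installed at
`inst/cli/drsprobe.R` (subcommands `simulate-scene`, `simulate-spectra`,
`track`, `evaluate`, `classify`).

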