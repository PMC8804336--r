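---
title: "Tracking an optical biopsy probe and classifying its spectra: methods"
author: "drsprobe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking an optical biopsy probe and classifying its spectra: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Diffuse reflectance spectroscopy (DRS) interrogates tissue at a single
contact point: broadband light is delivered through a fiber probe and the
diffusely reflected spectrum discriminates tumor from normal tissue. To turn
point measurements into a map that a surgeon or pathologist can use, two
things must happen at once: the probe tip must be localized in the camera
view at every frame, and each acquired spectrum must be scored in real time.
`drsprobe` implements this pipeline offline and end to end — synthetic scene
and spectra generators with exact ground truth, camera calibration, marker
detection, Kalman tip tracking, spectral preprocessing, classification, and a
session orchestrator — so that every stage is testable without access to
clinical recordings.

## Coordinate and color conventions

Frames are arrays `c(height, width, 3)` with RGB in `[0, 1]`; `x` indexes
columns, `y` rows, `y` grows downward. Hue is in degrees `[0, 360)`.
Probe yaw is the counter-clockwise angle of the probe axis on the displayed
image, taken modulo 180; the benchtop assumption is that yaw stays in
(0, 180), so the tip is the lower (larger-`y`) end of the midline. Both
endpoint rules are implemented (`tip_rule = "max_y"` or `"min_y"`) because
the geometry alone cannot distinguish them; the default matches a probe
descending into the frame from the top.

## The scene generator

The generator draws the probe as the 2-D projection of a cylinder: a rotated
rectangle of `probe_diameter_mm` width carrying a colored marker band of
`marker_length_mm` (default 70 mm, hue 120° for green or 180° for cyan),
plus a short unmarked ferrule of `tip_offset_mm` between the band and the
physical tip, so the tip and the marker end are distinct, testable points.
The paper-style geometry does not fix the ferrule length; it is exposed as
configuration with a 5 mm default. The background is a field of smooth
colored blobs with hues drawn from the purple–red–yellow arc (`c(300, 30)`,
wrapping through 0°), the gamut of biological tissue; this stresses the
detector with saturated warm colors without containing the marker hues.
Rendering is anti-aliased (~1 px soft edges), deterministic given the seed,
and adds luminance noise of sd 0.01 per pixel. Occlusion spans cover a
configurable fraction (default 0.8) of the band from the tip end with a
background-colored patch.

What the generator does **not** emulate: specular highlights, cast shadows,
motion blur, lens distortion, or photorealistic tissue texture. Passing the
tracking tests therefore demonstrates the correctness of the geometry and
the estimation chain under clean conditions, not clinical robustness; the
tracking error bounds asserted on synthetic video (2 px) are deliberately
tighter than what hand-labeled clinical video yields (about 4 px at
640 × 480).

## Detection

Each frame is resized to 640 × 480 and blurred with an 11 × 11 Gaussian
(σ = 2). The blur is a separable shift-and-add convolution with replicated
edges — numerically the same kernel as an FFT convolution but an order of
magnitude faster at video resolution, and it maps constant frames to
themselves exactly. Segmentation thresholds hue, saturation and value
jointly; the paper-style description names only hue and saturation, so the
value bounds default wide (`val ≥ 0.25`) and mainly reject near-black
pixels. Default bands are green hue 90–150°, cyan 160–200°, saturation
≥ 0.35. Two erosions followed by two dilations with a 5 × 5 disc remove
impulsive noise; the largest connected component above 200 px² is kept, with
exact-area ties broken by the smaller (row, column) bounding-box corner.

Edges come from a Hough transform over the component's boundary pixels at
1 px × 1° resolution, with sub-bin refinement by a 3 × 3 centroid. Peaks
must carry votes proportional to the component extent (30% of the larger
bounding-box dimension); this is what rejects curved boundaries — a circular
blob has parallel tangent pairs but no bin concentrates enough votes. The
two edges must be parallel within 5° with a separation of 5–150 px, and the
midline is their bisector computed in normal form (θ, ρ), which stays
numerically stable for near-vertical probes where slopes blow up.

The tip is found by sampling the mask along the midline at 1 px steps (with
±1 px perpendicular tolerance and closing of gaps ≤ 2 samples); the extreme
transitions of this 1-D profile are the two candidate ends, the configured
rule picks one, and the tip is displaced `tip_offset_px` beyond it. An
optional `band_px_range` rejects detections whose band length is
inconsistent with the expected marker — this is how partially occluded
markers are turned into honest misses for the tracker to coast over rather
than corrupt measurements.

## Tracking

A standard linear Kalman filter over state (x, y, vx, vy) with a
constant-velocity transition. Defaults: Q = diag(0.01, 0.01, 0.1, 0.1) px²,
R = diag(4, 4) px² (the observed detection jitter is below 2 px on synthetic
scenes), initial covariance 100·I. The covariance update uses the Joseph
form, which keeps it symmetric positive-definite over arbitrarily many
cycles. The track initializes its velocity from the first two detections
(two-point initialization), which makes noise-free constant-velocity input
pass through exactly; after 15 consecutive misses (`max_coast`, half a
second at 30 fps) the track is dropped until re-detection. Frames emitted
during misses are labeled `source = "predicted"`.

## Calibration and the pixel scale

Planar (checkerboard) calibration in closed form: per-view homographies by
the normalized DLT, two linear constraints per view on the image of the
absolute conic, intrinsics from the null vector, per-view rotations
re-orthonormalized by SVD. Lens distortion is not estimated — nothing
downstream uses it, and tracking error is reported in the undistorted
pinhole approximation. Corner *detection* is standard tooling and out of
scope; the module consumes point correspondences.

Millimetre conversion uses the fronto-parallel convention
`mm/px = 10 · d_cm / f_px` with `f` the mean focal length: at f = 1070 px
and 30 cm working distance one pixel spans 0.2804 mm, consistent with
published pixel/mm error pairs at that distance. This convention is the
package's explicit choice; a report states errors in both units so the
assumption is auditable.

## Spectral preprocessing

The processing order is fixed and logged in the dataset metadata:
reference normalization `(raw − dark) / (white − dark)`, Savitzky–Golay
smoothing, trim/resample, outlier flagging, then per-site averaging.
Flagging precedes averaging so that no-contact replicates cannot
contaminate a site mean. Savitzky–Golay defaults are window 11, order 3 —
narrow enough to preserve hemoglobin-scale features at 0.5 nm resolution,
wide enough to suppress shot noise; the filter reproduces polynomials up to
its order exactly, including at the edges. The analysis grid is
468–720 nm at 0.5 nm (505 points) by linear interpolation.

The outlier rule is deliberately value-level: residuals are taken against
the cohort median spectrum, and a value is outlying when it is more than
1.5 raw (unscaled) median absolute deviations from the residual median. A
spectrum is discarded when more than 75% of its values are outlying. The
75% row threshold encodes the phenotype being targeted: a no-contact "air"
spectrum sits near unit reflectance across the whole band, whereas a
legitimately offset tissue spectrum (contact pressure, illumination drift)
deviates modestly and only at some wavelengths. A per-row summary score
with a MAD cut, the obvious alternative, is self-scaling — for any
continuous unimodal score distribution it flags a fixed ~25–30% of healthy
rows — so it cannot achieve a low false-flag rate under any generator
settings; the value-level form does not have this defect. The rule,
threshold and scope are recorded in the output metadata. An all-identical
cohort has zero MAD and flags nothing.

## The spectra generator

Raw replicates are built as `dark + (white − dark) · r(λ) · (1 + ε)`, so
zero-noise data invert exactly under the normalization equation. Class mean
reflectance curves are Gaussian-bump mixtures over a flat baseline, with the
tumor class redder and dimmer around 560 nm; sites within a class vary by a
gain and a mild spectral tilt (both proportional to `noise_sd`), replicates
within a site by a gain (sd `noise_sd/2`) and per-point noise (`noise_sd`,
default 3%). Twenty replicates per site mirrors the standard acquisition
protocol. Outlier replicates are near-unity reflectance, emulating lack of
probe contact. The generator does not emulate chromophore physics,
wavelength-dependent detector response, or fluorescence; classification
results on it validate the pipeline's statistics, not clinical accuracy.

## Classification

Sites — not individual replicate spectra — are the cross-validation unit:
replicates of one site are exchangeable, and letting them straddle a fold
boundary would leak. Patient-grouped folding is available
(`group_by_patient = TRUE`) but off by default, since stratification is by
class. The plan deals each class's shuffled sites round-robin into folds
with a rotating offset, so per-fold class counts deviate from perfect
stratification by at most one site, and every site is tested exactly once
per repeat; 5 folds × 5 repeats is the default design.

Inside every training fold, and only there, features are z-scored
(population sd, constant features mapped to 0) and the top 100 wavelengths
by absolute Welch t statistic are kept. Four families are provided:
gradient-boosted trees with exact split finding (shrinkage 0.3, depth 6 —
the exact method places thresholds mid-gap between training values, which
matters at small n), histogram/leaf-wise boosted trees (31 leaves,
shrinkage 0.1), a single-hidden-layer perceptron, and an RBF support vector
machine with probability calibration. Metrics are accuracy, sensitivity and
specificity (tumor positive) and AUC, each in percent as mean ± sd over all
test folds; folds whose test split contains one class get an undefined AUC
and a warning. Single spectra are scored through the trained model to a
tumor probability; 0.5 is the display threshold, and the overlay color
interpolates linearly from green (normal) to pink (tumor).

## Session orchestration and evaluation

`run_session()` streams a scene through detection and tracking; at each
trigger frame the current smoothed tip becomes a biopsy site whose footprint
is the probe ferrule (0.125 in = 3.175 mm diameter converted through the
pixel scale), scored through the classifier when one is supplied. Sites are
re-projected onto all subsequent frames, and the archive (site registry,
track, config snapshot, log, annotated PNGs) reproduces bit-identically
under the same seed. Tracking accuracy against manual labels reports
per-axis RMSE, maximum and minimum absolute error in pixels and
millimetres; with two label sets each is evaluated separately and their
mean is the headline, since pooling and averaging differ only in the third
decimal on the data sizes involved but the choice should be visible.

## Problem sizes and numerical choices

The test suite and the acceptance script use a 600-frame tracking sequence
(plus a 240-frame occlusion sequence), 30–40-site spectral datasets with 20
replicates per site, and 5 × 5 cross-validation; these sizes give stable
statistics while keeping a full run in the minutes range on one core.
Degenerate inputs fail loudly: references with `white = dark` name the
offending wavelength, grids must match exactly, fewer than 4 homography
correspondences or 3 calibration views are errors, and a non-positive-
definite track covariance aborts the update. Real-time throughput (30 fps
video, 80 spectra/s) is a documented performance goal of the original
instrument, not something this offline implementation asserts.

## Known limitations

Single marker, single instrument; 2-D only (roll and pitch are unobservable
from one camera and never estimated); no learned detectors or trackers; no
chromophore-model fitting; benign or regressed-tumor classes are out of
scope. Classification numbers on synthetic spectra say nothing about
clinical discrimination — they verify leakage-free mechanics, calibration
of chance behavior, and monotonicity in class separation.
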