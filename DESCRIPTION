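Package: drsprobe
Title: Optical-Probe Tip Tracking and Diffuse Reflectance Spectra Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline pipeline for color-marker based tracking of a diffuse
    reflectance spectroscopy (DRS) probe in RGB video and for real-time-style
    tumor/normal classification of the acquired spectra. Provides synthetic
    scene and spectra generators with known ground truth, planar (checkerboard)
    camera calibration for the pixel-to-millimetre conversion, HSV marker
    segmentation with Hough-transform edge and midline estimation, Kalman
    filtering of the probe tip trajectory, reference normalization and
    Savitzky-Golay smoothing of raw spectra, robust outlier removal, repeated
    stratified cross-validation over several classifier families, and a
    session orchestrator that maintains an annotated biopsy-site registry and
    evaluates tracking accuracy against manually labeled tip positions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    signal,
    xgboost,
    e1071,
    nnet,
    pROC,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
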