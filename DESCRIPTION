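Package: beeforage
Title: Quantifying Bumblebee Foraging on Flower Patches from Video Detections
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for turning per-frame bumblebee detections from tiled
    video object detection into behavioural statistics. Covers pixel/mm
    calibration and quadrat geometry, tile-grid bookkeeping, confidence
    filtering and duplicate bounding-box merging, F1 evaluation against
    manual annotations, HSV colour-band flower segmentation with flower
    cover and optimal-flower-colour estimation, circular-hue colour
    distance heatmaps, patch attractiveness and cover-standardised
    carrying capacity, on-flower time budgets, and an AIC-based
    linear/mixed model selection ladder with residual diagnostics and
    heteroscedasticity-robust standard errors. Includes a seed-controlled
    synthetic scene and detection-stream generator with ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
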