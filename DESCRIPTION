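Package: eyefeatures
Title: Detection and Measurement of Eye Features in Color Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Multistage extraction of eye features from frontal color face
    images: pupil/iris center localization with a dark-tuned fast radial
    symmetry transform, iris radius estimation by radial gradient
    projection, pixel-wise sclera probability from a linear-margin color
    classifier calibrated with Platt scaling and compiled to a 24-bit
    lookup table, and eyelid shape recovery by Monte Carlo sampling of a
    two-parabola deformable eye model. Includes normalized center/radius
    error metrics and pixel-classification measures for evaluation, plus
    a parametric synthetic eye/face renderer with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
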