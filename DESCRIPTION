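Package: pesttrack3d
Title: Multi-Target 3D Trajectory Tracking of Nocturnal Insects in Stereo
    Thermal-Infrared Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recovering three-dimensional flight trajectories of
    nocturnal insects filmed with a parallel binocular thermal-infrared rig.
    Provides Gaussian-mixture background modelling with morphological
    clean-up and size filtering for motion-blurred warm targets, rule-based
    fusion of appearance and motion detections, a population-aware
    tracking-by-detection algorithm with velocity-adaptive IOU gating and
    Kalman motion models, disparity-based stereo triangulation of paired 2D
    tracks, CLEAR-MOT and detection metrics against MOT16-format ground
    truth, and a ground-truthed synthetic stereo scene generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
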