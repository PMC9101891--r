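Package: gazefilter
Title: Stable Pupil-Corneal-Reflection Gaze Tracking with Adaptive Kalman Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stable video-based gaze estimation from infrared eye
    imagery. Provides a synthetic eye-image generator with full ground truth;
    fast pupil localization by kernelized correlation-filter (KCF) tracking
    with grayscale features; high-precision pupil ellipse extraction using
    star-ray edge selection restricted to the left and right pupil flanks
    (robust to eyelid occlusion) together with corneal-glint centroiding;
    second-order polynomial calibration from pupil-corneal-reflection vectors
    to on-screen points of regard; and constant-velocity / constant-acceleration
    Kalman filters whose measurement-noise covariance adapts to the estimated
    gaze speed, which suppresses point-of-regard fluctuation during fixation.
    Includes end-to-end evaluation tasks (nine-point fixation, smooth-pursuit
    polyline with dwells) and tracking precision metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
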