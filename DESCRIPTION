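Package: facepose
Title: Head-Posture Measurement from 2D Facial Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates clinical head posture (roll, pitch, yaw) and metric
    head position from per-frame 2D facial landmark observations by fitting
    a fixed 68-point 3D face model under a pinhole camera, with metric scale
    anchored by a standard 65 mm interpupillary distance and a residual-based
    goodness-of-fit confidence. Includes a synthetic landmark generator
    (pose trajectories, pixel noise, occlusion, dropped frames, and a
    43-pose fixation-target protocol), per-frame accuracy evaluation with
    confidence filtering and operational-range derivation, and
    method-comparison statistics (Pearson correlation, linear regression,
    Bland-Altman limits of agreement, two-way random-effects intraclass
    correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
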