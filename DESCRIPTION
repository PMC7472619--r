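Package: squatkin
Title: Dual-System Single Leg Squat Kinematics and Concurrent Validity
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint kinematics of the single leg squat measured simultaneously by an
    optical marker-cluster system and by body-worn orientation sensors, together with
    the statistics needed to judge their agreement. Provides quaternion machinery
    (swing-twist decomposition into tilt/sway/twist, intrinsic
    sagittal-frontal-transverse Euler sequences, spherical linear interpolation), a
    gold-standard optical pipeline (gap filling, zero-phase Butterworth filtering,
    SVD Procrustes cluster pose fitting), a sensor pipeline operating on orientation
    quaternions, peak-knee-flexion extraction, concurrent-validity statistics
    (Shapiro-Wilk gated Pearson/Spearman correlations, mean differences with t-based
    confidence intervals), and a rigid-body squat simulator that renders noisy marker
    and sensor streams with ground truth retained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
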