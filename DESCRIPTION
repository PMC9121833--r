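Package: popsubspace
Title: Population Activity Subspaces, Task-Feature Decoding, and Sleep
    Reactivation for Neural Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of simultaneously recorded neural population activity
    across the phases of a trial-based maze task. Builds per-phase population
    firing-rate vectors, quantifies the linear separability of trial and
    intertrial-interval activity in low-dimensional principal-component
    projections, decodes binary task features (choice direction, cue position,
    outcome) with leave-one-out cross-validated logistic regression against
    label-shuffle chance levels, measures the geometry of decoding axes
    (between-phase and between-feature angles, cross-phase decoding),
    classifies sessions by behavioral learning via piecewise robust regression
    of the cumulative reward curve, and quantifies reactivation of
    feature-specific activity in pre- versus post-training slow-wave sleep
    with a rank-correlation median-difference statistic. Includes a seeded
    synthetic-session generator with implanted ground truth for parameter
    recovery and null calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
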