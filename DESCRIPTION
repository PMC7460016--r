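Package: motorkin
Title: Markerless Motor Assessment from Skeleton Time Series with
    Test-Retest Reliability Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes motor-function variables from 20-joint markerless
    skeleton recordings of a standardized six-maneuver protocol (resting
    stance, T position, finger-to-nose, sideways step, 45-degree monopodal
    balance, chair-to-stand) and quantifies their relative and absolute
    test-retest reliability. Includes a synthetic motion and depth-sensor
    simulator with known ground truth, bilateral arm-flap ("greeting")
    event detection and protocol segmentation, per-maneuver kinematic
    feature extraction, and a reliability engine: one-way and repeated
    measures ANOVA with Mauchly's sphericity test and Greenhouse-Geisser
    correction, intraclass correlation coefficients with exact F-based
    confidence intervals, standard error of measurement, coefficient of
    variation, standardized between-attempt effect sizes with bootstrap
    intervals, and activity-group comparisons.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    signal,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
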