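Package: gaitrel
Title: Reliability Analysis of Wearable-IMU Running Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying the test-retest reliability of discrete
    lower-extremity joint angles measured with inertial motion capture during
    over-ground running. Segments continuous recordings into gait cycles from
    maxima of the right-foot anterior-posterior position, time-normalizes each
    cycle to 101 points, extracts initial and peak joint angles plus
    spatio-temporal parameters, and estimates between-day, within-day, and
    calibration reliability via the absolute-agreement intraclass correlation
    ICC(A,1), the standard error of measurement, and the minimal detectable
    change. Includes a hierarchical variance-component simulator with
    analytically known ground-truth ICCs, and a random-intercept mixed-model
    analysis relating between-day joint-angle differences to differences in
    running speed, stride frequency, and surface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
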