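Package: fallrisk
Title: Wearable Inertial Sensor Test Battery for Multifactorial Fall Risk
    Assessment
Version: 1.0.0
Authors@R:
    person("fallrisk", "maintainers", email = "fallrisk@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving fall-risk measures from body-worn inertial
    sensors (low back, upper and lower legs) recorded during a seven-subtest
    battery: quiet-standing sensory integration, limits of stability,
    five-times sit-to-stand, timed up and go, knee motor function, choice
    reaction and falls-efficacy questionnaires.  Includes gait-event and
    turn detection from shank angular velocity, sit-to-stand segmentation,
    postural-sway scoring, a 155-measure catalogue, univariate screening by
    two-sample t-tests and ROC analysis, permutation-importance ranking, and
    six cross-validated faller classification models.  A synthetic-data
    module generates signal-level sessions with ground-truth annotations and
    feature-level faller/non-faller cohorts so the whole pipeline is testable
    without access to a clinical cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    quadprog,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
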