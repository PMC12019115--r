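Package: vmadapt
Title: Visuomotor Rotation Adaptation Analysis for Cursor and Camera-Control Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for visuomotor rotation experiments
    in which input-device movements either translate a cursor over a static
    scene (Point), pan and tilt a camera so the scene moves around a fixed
    cursor (Look), or do so with inverted gains (Inverted Look). Provides an
    equated task geometry for the three contexts, experiment schedule builders
    with an adaptive 1-up/1-down time-limit staircase, a state-space learner
    with hand-vector-centred generalization for synthetic cohorts, trajectory
    preprocessing (glitch rejection, uniform resampling, zero-phase Butterworth
    filtering), hand-angle extraction at peak speed and take-off, cycle/period
    aggregation with after-effect, transfer and baseline-corrected
    generalization measures, and a statistical layer (mixed-design ANOVA with
    partial eta squared, marginal-mean contrasts, t tests, BIC-approximate
    Bayes factors, random-intercept mixed regressions).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    withr,
    signal,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
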