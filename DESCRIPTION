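Package: acttime
Title: Simulation and Survival-Based Analysis of When-to-Act Decisions in a Dots Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying the timing of self-initiated actions in a
    reward-accumulation ("dots") task. Provides a generative simulator of the
    task (sigmoid reward schedule, balanced and biased offer distributions,
    blocked inter-trial intervals, a proportional-hazards response agent with
    trial-history effects, and event-locked BOLD channels with injectable
    effect sizes); a discrete-time Cox proportional-hazards model of action
    time with a Breslow baseline estimator and a per-trial "deterministic
    action time" computed as the expectation of the fitted survival curve;
    linear mixed-effects analyses of observed and deterministic action time
    with Wald chi-square inference; an ROI BOLD time-course pipeline (volume
    censoring, normalization, upsampling, epoching, per-timestep OLS models
    including psychophysiological-interaction regressors) with leave-one-out
    group-peak significance testing; and a configuration-driven pipeline
    runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    RNifti,
    optparse,
    jsonlite
Config/testthat/edition: 3
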