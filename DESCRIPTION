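Package: trajsurv
Title: Linking Longitudinal Biomarker Trajectories to Time-to-Event Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying how a noisily measured longitudinal biomarker
    drives a survival hazard. Provides a closed-form Lambert-W simulator for
    event times under Exponential and Weibull hazards with a linear
    time-varying trajectory, four estimators of the link parameter (two-step
    regression calibration, last-value-carried-forward time-dependent Cox,
    maximum-likelihood Weibull shared-parameter joint model, and a Bayesian
    joint model via Metropolis-within-Gibbs), and a simulation-study harness
    computing Type I error, bias, coverage and mean squared error across
    scenario grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    survival,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
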