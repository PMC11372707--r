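Package: forcefluct
Title: Magnitude and Structure of Force Fluctuations in Bimanual
    Force-Tracking Tasks
Version: 0.1.0
Authors@R:
    person("SENDA", "Analysis Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the magnitude (coefficient of variation)
    and temporal structure (detrended fluctuation analysis scaling exponent,
    sample entropy) of isometric force fluctuations recorded during bimanual
    constant and role-differentiated force-tracking tasks, together with a
    synthetic cohort-sequential data generator (colored-noise force signals,
    MoCA/CERAD-based cognitive-impairment screening labels, measure-scale
    outcome simulation) and linear mixed-effects inference with stepwise
    model building, AIC selection, likelihood-ratio tests and t-based
    effect sizes r.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
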