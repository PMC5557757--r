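Package: tactsens
Title: Simulation and Analysis of Tactile Sensitivity Experiments with
    Autonomic and Psychophysical Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating and analysing a four-task tactile
    sensitivity protocol combining autonomic and perceptual measures:
    event-related skin conductance responses (SCR) to electrical stimuli,
    transformed up-down (2-down/1-up) adaptive staircases for two-point
    discrimination and touch detection thresholds, a constant-stimuli
    touch comparison task fitted with a cumulative-logistic psychometric
    function, and the accompanying statistical battery (pooled t with
    Cohen's d, mixed-design ANOVA with partial eta squared, Bonferroni
    pairwise post-hocs, Mann-Whitney U with normal approximation, Pearson
    correlation, and rank-based Benjamini-Hochberg false discovery rate
    control). A seeded synthetic-cohort generator produces skin
    conductance traces, staircase trial sequences, constant-stimuli
    responses and questionnaire scores with the dependence structure the
    analyses assume, so the whole pipeline is testable without access to
    participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
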