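Package: contextdep
Title: Simulation and Analysis of Central Tendency in Visual Space and
    Time Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to simulate and analyse psychophysical experiments on
    context dependency (central tendency, regression to the mean) in the
    visual perception of spatial lengths and temporal intervals. Provides
    block-randomized stimulus schedules, Bayesian ideal-observer
    simulation of reproduction and two-interval discrimination tasks, a
    QUEST adaptive staircase, maximum-likelihood cumulative-Gaussian
    psychometric fitting with Weber fractions, the
    offset/regression-index/BiasCD/CV/RMSE metric suite for reproduction
    data, control-task metrics, and the group-level statistics
    (one-sample t, Cohen's d, Mann-Whitney U) used to evaluate them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
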