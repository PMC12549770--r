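Package: rlwmlba
Title: Joint Modeling of Choice and Reaction Time in Reinforcement
    Learning Working Memory Tasks
Version: 0.1.0
Authors@R:
    person("RLWM", "Modeling Team", role = c("aut", "cre"),
           email = "modeling@example.org")
Description: Tools for simulating and fitting the RLWM-LBA model: a dual-system
    instrumental learning model that mixes an incremental reinforcement
    learning module with a fast, capacity-limited, decaying working memory
    module, and maps the mixed choice policy onto a linear ballistic
    accumulator (LBA) likelihood for joint choice and reaction-time data.
    Includes a generator for the RLWM task (blocks of set size 2-5 with
    controlled stimulus interleaving), hierarchical Bayesian MAP estimation
    with non-centered subject deviations, parameter-recovery and posterior
    predictive utilities, synthetic cohort generation with planted covariate
    effects, Bayesian linear / logistic / ordinal regression with
    Savage-Dickey Bayes factors, and a repeated cross-validated ridge
    regression pipeline for prediction analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
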