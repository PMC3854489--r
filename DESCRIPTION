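Package: hierseq
Title: Hierarchical and Flat Reinforcement-Learning Models of the Two-Stage Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the two-stage sequential decision task with resetting
    binary reward probabilities, implements two families of reinforcement
    learning agents -- a flat hybrid of model-based and model-free Q-learning,
    and a hierarchical model in which a goal-directed controller selects
    between single actions and open-loop two-action sequences (options) --
    and provides the analysis stack used to compare them: stay-probability
    tables and regressions, reaction-time contrasts, conditional-inference
    style recursive partitioning, per-subject MAP fitting with Laplace model
    evidence, and random-effects Bayesian model selection with family-level
    inference. Ships a synthetic-cohort generator with ground-truth labels
    for parameter- and model-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
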