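Package: twostepRL
Title: Simulation and Hybrid Model-Based/Model-Free Analysis of the
    Two-Step Markov Decision Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying habitual versus goal-directed control in the
    sequential two-step Markov decision task. Provides the task environment
    (fixed 70/30 first-stage transitions, Gaussian random-walk reward
    probabilities with reflecting boundaries), a seven-parameter hybrid
    reinforcement-learning agent combining SARSA(lambda) temporal-difference
    learning with Bellman model-based planning, maximum a posteriori parameter
    estimation on an unbounded scale with multistart quasi-Newton optimisation
    and an optional one-step empirical-Bayes (EM) prior, a synthetic-cohort
    generator with a configurable break-condition by working-memory moderation
    of the goal-directed weight, and group-level mixed-effects inference
    (condition effects, moderation, simple effects by re-centering, Bonferroni
    correction, stay-probability diagnostics). Includes end-to-end pipelines
    for parameter-recovery and effect-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    lmerTest,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
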