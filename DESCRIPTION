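Package: noveltybandit
Title: Novelty-Bonus Reinforcement Learning on a Three-Armed Bandit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and model-based analysis of a three-armed bandit
    task with a novelty manipulation. Generates task designs in which one
    option is periodically replaced by a never-seen image, simulates
    delta-rule/softmax agents that assign separate initial values to novel
    and pre-familiarized stimuli, fits the four-parameter model (and its
    constrained, no-novelty-bonus variant) by bounded multi-start maximum
    likelihood, compares the nested models with likelihood-ratio tests,
    computes behavioural outcome measures (amount won, first-presentation
    choice rates, persistence runs), and exports value and prediction-error
    parametric-modulator event tables for model-based fMRI analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lhs,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
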