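Package: banditSI
Title: Hidden-State Inference and Reinforcement-Learning Analysis of
    Probabilistic Reversal Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and likelihood-based analysis of the two-armed
    bandit (probabilistic serial reversal learning) task. Implements a
    family of behavioral agents -- random choice, win-stay/lose-shift,
    choice kernel, Q-learning with bias, choice-kernel, asymmetric,
    counterfactual, forgetting and Pearce-Hall variants, and Bayesian
    hidden-state inference via an HMM forward filter -- in both generative
    and session-conditioned modes; maximum-likelihood fitting with
    multi-restart bounded optimization and BIC model comparison; model
    recovery via confusion and inversion matrices; behavioral summaries
    (reversal curves, trial-history elastic-net logistic regression,
    switch probability by history, strategy consistency); model-derived
    reward-prediction errors with synthetic two-channel photometry and
    time-warped cross-validated ridge regression with coefficients of
    partial determination; and population analyses on synthetic neural
    data (selectivity indices, trial-type PCA, balanced linear decoding,
    cross-condition generalization).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    glmnet,
    signal,
    e1071,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
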