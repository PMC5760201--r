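Package: assoclearn
Title: Associability-Modulated Reinforcement Learning for Loss and Gain
    Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of adaptive two-armed bandit loss/gain
    learning with hybrid Rescorla-Wagner/Pearce-Hall reinforcement learning
    models. Provides an adaptive task simulator, likelihoods and latent
    traces for value-learning models with and without an
    associability-gated learning rate, per-subject two-stage maximum
    likelihood estimation with a fixed inverse temperature, AICc-based
    random-effects Bayesian model selection with protected exceedance
    probabilities, behavioral validation analyses (performance sweeps,
    calibration, reaction-time and switching regressions, jackknife
    standard errors), group contrasts on model parameters, synthetic
    cohort generation, and export of z-scored trial-by-trial regressors
    for model-based neuroimaging.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lme4,
    car,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
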