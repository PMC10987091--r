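Package: grackleRL
Title: Reinforcement Learning Analysis of Two-Option Reversal Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for two-option colour-reward reversal
    learning experiments in wild-caught birds, built around great-tailed
    grackle data structures. Provides learning-criterion calculators
    (including legacy fixed- and sliding-window rules and their documented
    pathologies), a hierarchical Bayesian Rescorla-Wagner reinforcement
    learning model with softmax choice fitted via MCMC, multilevel Poisson
    models of trials-to-criterion and choice-option switches, agent-based
    forward simulation from posterior draws, an evolutionary algorithm for
    learning-parameter optimality under varying environmental stability and
    stochasticity, and a synthetic-cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    rjags,
    coda,
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
SystemRequirements: JAGS 4.x.y (http://mcmc-jags.sourceforge.net)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
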