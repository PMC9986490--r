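Package: gintercept
Title: Active Inference Agents for Locomotor Interception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A 60 Hz simulator of a locomotor interception task in which an
    agent controls its approach speed through a first-order pedal lag to
    intercept a target that changes speed semi-predictably, together with a
    neural active inference agent that learns action-conditioned negative
    expected-free-energy (G) values by a Q-learning-style bootstrap. The
    agent's per-step reward combines an instrumental term (log-likelihood of
    a prior preference over the agent-vs-required speed difference) with an
    epistemic term (squared prediction error of a learned forward model).
    Includes a sparse-reward deep Q-network baseline, an instrumental-only
    ablation, experiment orchestration, and time-to-contact anticipation
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
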