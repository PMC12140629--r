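Package: upecircuit
Title: Uncertainty-Modulated Prediction Error Microcircuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rate-based simulation of layer 2/3 cortical microcircuits in
    which somatostatin-positive (SST) and parvalbumin-positive (PV)
    interneurons learn, through local activity-dependent plasticity, the
    context-conditioned mean and variance of a Gaussian stimulus
    distribution, and pyramidal error neurons compute prediction errors
    that are divisively scaled by the learned uncertainty.  Provides
    generators for context-cued stimulus schedules, four circuit variants
    (feedforward positive and negative prediction-error circuits, a
    recurrent circuit with an internal representation neuron, and a
    two-area hierarchical circuit), closed-form steady-state oracles,
    scripted experiment protocols (mean and variance learning, mismatch
    probing, adaptive learning-rate comparison, prior-sensory weighting
    sweeps), and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
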