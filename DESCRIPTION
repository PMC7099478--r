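Package: neuromf
Title: Mean-Field Models of Conductance-Based Spiking Neuron Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates random excitatory/inhibitory networks of conductance-based
    spiking neurons (Adaptive Exponential Integrate-and-Fire, Hodgkin-Huxley and
    Morris-Lecar models) driven by Poissonian input, fits each model's
    input-output transfer function semianalytically from subthreshold membrane
    moments via a phenomenological effective threshold, and predicts spontaneous
    and stimulus-evoked population rates with a first- and second-order
    master-equation mean field validated against the network simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
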