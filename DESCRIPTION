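Package: hiddenpaths
Title: Effective Synaptic Interactions in Partially Observed Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting how unobserved ("hidden") neurons reshape
    the synaptic interactions measured among a recorded subset of a nonlinear
    Hawkes (spiking GLM) network. Given a fully specified network and a
    recorded/hidden partition, the package computes hidden-subnetwork
    mean-field rates and gains, the hidden-network linear response by
    frequency-domain matrix inversion, and the effective baselines and
    effective coupling filters among recorded neurons, together with their
    decomposition into contributions from directed paths through hidden
    neurons. Includes seeded Erdos-Renyi (mixed-synapse and Dale's-law) and
    Watts-Strogatz network ensemble generators, ensemble statistics of the
    deviation between effective and true synaptic weights with analytic
    strong- and weak-coupling predictions, closed-form worked circuits
    (feedforward inhibition and a degenerate 4-neuron motif), and a
    discrete-time spike-train simulator for validating the mean-field theory.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
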