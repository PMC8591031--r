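Package: spikeworks
Title: Modular Behaviour-Driven Spiking Neural Network Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lightweight, modular framework for building and simulating
    brain-inspired neural networks. Networks are assembled from neuron groups
    and synapse groups that carry no dynamics of their own; all computation
    lives in exchangeable behaviour modules that are ordered by numeric keys
    into a single global execution pipeline. The package bundles
    leaky integrate-and-fire and Izhikevich neuron models, SORN-style
    spike-timing-dependent plasticity, synaptic weight normalization,
    intrinsic plasticity, refractory periods and a diffusing-messenger
    homeostasis rule, together with a tag-based object retrieval system,
    expression-string recorders, a differential-equation engine with physical
    units, partitioning of large sparse synapse groups into dense local
    blocks, an evolutionary parameter optimizer, and a storage manager for
    organizing simulation runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    R6,
    digest,
    graphics,
    jsonlite,
    rhdf5,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
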