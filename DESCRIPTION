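Package: snnanimat
Title: Self-Learning Spiking Neural Networks Controlling a Simulated Animat
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation of small spiking neural networks built from Izhikevich
    neurons coupled by Tsodyks-Markram synapses with axonal conduction delays
    and delay-aware, trace-based multiplicative spike-timing-dependent
    plasticity (STDP). Because depression is triggered by spike arrival
    (emission time plus axonal delay), STDP potentiates the fastest
    spike-conducting route to a neuron and depresses slower alternatives (the
    shortest-pathway rule). The package provides network builders for the
    canonical motifs and the seven-neuron sensorimotor network, pulse-train
    stimulation protocols for classical (Pavlovian) conditioning with
    conditional/unconditional stimulus pairing, and a closed-loop
    differential-drive robot (animat) in a 2D obstacle arena for operant
    conditioning, including relearning after the sonar inputs are swapped.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
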