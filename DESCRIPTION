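Package: ehhsim
Title: Extended Hodgkin-Huxley Network Simulation with Ring-Partitioned
    Gap Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based simulation of extended Hodgkin-Huxley (eHH)
    neural networks: generalized three-branch gate rate functions, serially
    chained multi-compartment cells, calcium-like auxiliary states, and
    gap-junction electrical coupling with a voltage-difference-dependent
    conductance. Gap-junction currents can be computed densely or through a
    ring-partitioned systolic schedule that emulates a multi-accelerator
    layout, with connectivity weights generated on the fly by the
    counter-based Squares random number generator (uniform or
    probit-transformed Gaussian). Ships fully parameterized presets for the
    original squid-axon Hodgkin-Huxley cell and a three-compartment inferior
    olive cell, a forward-Euler time stepper with stimulus and trace
    handling, an analytical performance model of the dataflow hardware
    implementation (DRAM/interconnect throughput, memory-block counts, tick
    counts, bottleneck prediction), NeuroML-subset channel import, a native
    JSON configuration format, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
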