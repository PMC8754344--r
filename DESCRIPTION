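Package: retsim
Title: Compartmental Simulation of Retinal Direction-Selective Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.net",
    role = c("aut", "cre"))
Description: Simulates passive multicompartment retinal neurons driven by
    structured visual stimuli through stochastic ribbon synapses. Builds
    starburst amacrine cell (SAC) networks and SAC-to-ganglion-cell circuits
    with retina-specific connectivity rules, computes centrifugal- and
    direction-selectivity indices from the simulated voltage, and searches
    the synaptic parameter space with a multi-objective genetic algorithm
    for configurations that reproduce the centrifugal preference of SACs.
    Includes SWC morphology input/output, synthetic planar morphologies, a
    visual stimulus compiler (expanding/collapsing rings, alternating bars,
    flicker noise), and a backward-Euler branched-cable integrator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
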