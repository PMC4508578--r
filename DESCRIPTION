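Package: gridtorus
Title: Spiking Continuous-Attractor Networks for Grid Firing and Theta-Nested Gamma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of twisted-torus continuous-attractor
    networks of exponential integrate-and-fire neurons, the excitatory-
    inhibitory circuit architecture proposed for grid cells in layer 2 of
    the medial entorhinal cortex.  Provides the network construction
    (distance-dependent synaptic profiles, scaled or probabilistic
    connectivity, I-I and E-E variants), a fast compiled simulation engine
    with theta drive, velocity input, place-cell resetting and per-cell
    current noise, and the full analysis stack: spatial rate maps,
    autocorrelograms, gridness score, Skaggs spatial information and
    sparsity, gamma oscillation strength and frequency from inhibitory
    synaptic currents, bump-attractor fitting, drift and seizure metrics,
    and parameter-sweep orchestration with phase-map aggregation and
    dependence statistics (R squared, maximal information coefficient).
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
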