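Package: detoursim
Title: Spiking-Network Simulation of Detour Behavior Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates an agent solving the inward semitransparent-V detour
    task with a small spiking network that selects between an egocentric
    direct-approach strategy and an allocentric wavefront-map strategy.
    Implements Izhikevich regular-spiking units, leaky-integrator readouts
    with argmax selection, an adjustable inhibitory weight from the barrier
    channel onto the direct-approach channel, a ray-cast camera in a 2D
    arena, occupancy-grid wavefront planning, and an experiment harness
    that sweeps inhibition level and neural population size while measuring
    time spent in the barrier zone.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    ggplot2,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
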