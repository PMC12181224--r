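Package: fplr
Title: Fixed Point-Learning Rate Models of Calcium-Based Synaptic Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators for calcium-controlled synaptic plasticity in which a
    weight update is specified by a fixed point (where the synaptic weight is
    headed) and a learning rate (how fast it gets there) per calcium region.
    Implements the classic two-threshold calcium rules of the
    Shouval-Bear-Cooper family, the bistable Graupner-Brunel rule and its
    simplified variant, one- and two-dimensional fixed point-learning rate
    (FPLR) rules including multi-stable basins of attraction and a
    protein-synthesis-gated late phase, exponentially decaying spike-driven
    calcium traces with region "bar codes", canonical plasticity protocols
    (frequency-dependent plasticity, spike-timing-dependent plasticity,
    late-phase LTP/LTD), and a leaky-integrator place-field simulation of
    behavioral-timescale plasticity (BTSP) on a circular track. Ships the
    parameter presets used by the canonical experiments and a command-line
    interface for running protocol sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
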