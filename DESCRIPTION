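Package: neuroclock
Title: Clustered Spiking Recurrent Networks that Learn and Replay Spatiotemporal Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis of a clustered excitatory-inhibitory
    spiking recurrent network that self-organizes into a cyclic neural clock
    through voltage-based spike-timing-dependent plasticity, inhibitory
    plasticity with a target rate, and periodic synaptic normalization, plus
    a supervised read-out layer that learns and autonomously replays
    higher-order spatiotemporal sequences (for example ABCBA). Includes
    adaptive exponential integrate-and-fire neuron dynamics with
    conductance-based synapses, piecewise-constant Poisson stimulation
    protocols, a fast compiled simulation engine, and the analysis tools
    used to verify the model: cluster-block weight matrices, full weight
    spectra, clock-period estimation, and replay decoding.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
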