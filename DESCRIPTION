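Package: plastadapt
Title: Behavioral Simulator of a Time-Multiplexed Synaptic Plasticity Adaptor Array
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Discrete-time behavioral simulation of a time-multiplexed,
    dynamically-assigned array of synaptic plasticity adaptors implementing
    spike-timing-dependent plasticity (STDP) and spike-timing-dependent delay
    plasticity (STDDP). Models the 26-bit address-event (AER) interface with
    its direct-mapped slot assignment and collision semantics, per-slot time
    window generators (deterministic digital down-counters and a stochastic
    mismatch variant), bistable 1-bit weight storage with LFSR-based stochastic
    expansion, write-through Master-RAM/local-cache coherence, and saturating
    4-bit weight and delay arithmetic. Includes synthetic input generators
    (Poisson trains, paired-pulse protocols), a leaky integrate-and-fire
    neuron stub, and experiment drivers for balanced-excitation,
    dynamic-assignment validation, and polychronization studies, plus a
    capacity calculator for the architecture's scaling arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
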