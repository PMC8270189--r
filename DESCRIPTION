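Package: lsosim
Title: Binaural Tuning and Inhibition Loss in a Model Lateral Superior Olive Neuron
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic simulation of lateral superior olive (LSO) neurons as
    conductance-driven integrate-and-fire models, with excitatory and
    inhibitory presynaptic spike trains generated as homogeneous or von
    Mises phase-locked Poisson processes. Provides tools to compute
    interaural level difference (ILD) and envelope phase tuning curves,
    modulation depth, Fano factors, and d-prime-like neuronal
    discriminability; to model age-related loss of inhibitory fibers with
    homeostatic amplitude compensation rules; and to assess population-level
    coding with mirrored bilateral neuron pairs. Includes a reproducible
    experiment driver with plain-text configuration and output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
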