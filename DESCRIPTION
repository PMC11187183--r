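Package: persistlick
Title: Persistent Licking Behavior, Prefrontal Spike-Train Analysis, and a
    Motor-Projecting Network Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the initiation and termination of persistent
    licking in head-fixed rodents and the cortical spiking activity that
    drives it.  Provides lick-microstructure statistics (moving-average
    initiation and termination bias), Bayesian adaptive kernel smoothing of
    spike trains, shuffle-based classification of single units into valence
    and movement-phase representations, population decoding with pseudo-data
    controls, cross-correlogram connectivity screening, a synthetic-session
    generator for all of the above, and a conductance-based spiking network
    model with short-term synaptic plasticity whose output spikes are
    converted to lick events by a nine-phase decision rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
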