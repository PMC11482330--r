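Package: spikecomms
Title: Between-Area Communication in Spatially Organized Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of between-area neural communication in
    layered networks of exponential integrate-and-fire neurons arranged on a
    periodic unit square with wrapped-Gaussian, distance-dependent wiring.
    Provides a fast forward-Euler spiking simulator whose excitatory/inhibitory
    balance can be destabilized in space (broad recurrent inhibition) or in
    time (slow inhibitory synapses), together with the population-statistics
    battery used to study how such destabilization shapes communication:
    pairwise spike-count correlations versus distance, factor-analysis shared
    covariance and participation-ratio dimensionality, and a reduced-rank
    regression communication subspace with cross-validated optimal rank. Two
    mechanism experiments (a superposition linearity test and a frozen-input
    macroscopic-chaos test) and fast toy signal fixtures complete the study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
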