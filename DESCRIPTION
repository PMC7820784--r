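Package: critnet
Title: Criticality and Ictal Phases in Small-World Hodgkin-Huxley Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates networks of conductance-based Hodgkin-Huxley neurons
    coupled on a directed Watts-Strogatz small-world graph and driven by a
    white-noise voltage-clamped node, and analyses the resulting activity for
    signatures of criticality. A stickiness parameter slows sodium-channel
    inactivation kinetics and moves the network between silent, subcritical
    (exponential), critical (power-law) and ictal (hypersynchronized) phases.
    Provides raster extraction, simultaneous-firing histograms, exponential /
    power-law / truncated power-law fits, percolation-style mean cluster
    size, phase classification, synthetic EEG (mean voltage), Welch power
    spectral density with high-frequency slope estimation, Morlet wavelet
    scalograms, and CSV/EDF export.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
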