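Package: smtrace
Title: Hidden Markov Model Analysis of Single-Molecule Intensity Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for kinetic analysis of single-molecule time series such
    as smFRET donor/acceptor photon-count traces. Simulates multi-channel
    traces from user-specified kinetic models with Poisson or Gaussian
    emission noise and photobleaching-coupled trace lengths, fits hidden
    Markov models per molecule by Baum-Welch maximum likelihood (supporting
    tied emissions and a detailed-balance constraint for systems at
    equilibrium), computes likelihood-ratio confidence intervals for fitted
    parameters, ranks candidate kinetic models by the Bayesian information
    criterion, provides a threshold-crossing dwell-time baseline, and
    clusters molecules on fitted parameters weighted by each molecule's own
    uncertainty to assess population heterogeneity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
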