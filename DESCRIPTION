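Package: bcscniche
Title: Stochastic Modeling of Breast Cancer Stem Cell State Transitions and
    Niche-Targeted Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build and simulate mass-action reaction networks of the
    breast cancer stem cell (BCSC) niche. Implements exact Gillespie stochastic
    simulation and step-anticipation tau-leaping (SAL) with a hybrid
    critical-reaction scheme, two-state continuous-time Markov chain estimation
    of epithelial-mesenchymal transition rates from marker data, a
    carcinogenesis hierarchy model with a time-varying symmetric/asymmetric
    division schedule that reproduces Gompertzian bulk tumor growth, Gompertz
    curve fitting, and in-silico single and pairwise inhibition screens of
    niche elements with extinction statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    minpack.lm,
    deSolve,
    yaml,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
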