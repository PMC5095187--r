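Package: divshift
Title: Diversification Rate Shifts from Higher-Level Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood estimation of piecewise-constant (skyline)
    speciation and extinction rates from higher-level phylogenies, i.e.
    ultrametric trees in which every clade descending a lineage at a cut
    time is collapsed to a single extant tip annotated with its species
    count. Provides the zero-modified-geometric descendant-count
    distributions of the linear birth-death process and their composition
    across rate intervals, the likelihood of a higher-level phylogeny
    under a birth-death-skyline model, exact simulation of trees
    conditioned on the number of extant species with rate shifts, clade
    collapsing, likelihood-ratio model selection for rate shifts, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
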