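Package: rgem
Title: Context-Specific Genome-Scale Metabolic Modeling with Multi-Omic
    Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constraint-based analysis of stoichiometric metabolic networks
    with transcriptomic and metabolomic data integration. Provides flux
    balance and flux variability analysis on a built-in linear-programming
    engine, GIMME context-specific subnetwork extraction from present/absent
    expression calls, translation of plasma metabolite fold changes into
    exchange-reaction bound constraints, artificial-centering hit-and-run
    sampling of the feasible flux polytope, Kolmogorov-Smirnov detection of
    differentially active reactions, correlated reaction sets, and
    wildtype-versus-knockout model comparison with subsystem breakdowns and
    stoichiometric metabolite-connectivity ranking. Ships a synthetic
    kidney-redox toy network generator so the whole pipeline is testable
    without external model downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
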