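Package: biplink
Title: Link Prediction and Evaluation for Bipartite Drug-Disease Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for predicting missing edges in bipartite two-mode
    networks such as drug-disease indication networks.  Implements
    elementary similarity-based scores (degree product, common-neighbour
    family, Katz), low-rank factorization scores (truncated SVD, PLSA
    fitted by expectation-maximization, non-negative matrix
    factorization), and a Bayesian degree-corrected stochastic block
    model sampled by single-node MCMC.  Includes an edge-holdout
    cross-validation harness reporting AUROC, AUPR, prevalence-normalized
    AUPR and top-k precision, a synthetic generator for planted-structure
    bipartite networks, and theoretical upper bounds on the fractions of
    missing edges and false positives implied by a measured AUROC.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
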