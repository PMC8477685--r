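Package: tryptnet
Title: Temporal Reproducibility of Metabolite Networks by Graphical Lasso
    and Bayesian Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sex-stratified analysis of urinary tryptophan-pathway
    metabolite networks at two timepoints. Estimates regularized
    partial-correlation networks (Gaussian graphical models) by the
    graphical lasso with BIC-selected penalty, and linear-Gaussian
    Bayesian networks by BIC hill climbing with bootstrap model
    averaging. Provides strong-edge extraction, a permutation network
    structure invariance test, Hamming distances between skeletons,
    temporal-reproducibility intersection and cross-method consensus
    reporting, together with a synthetic cohort generator with planted
    dependence structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
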