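Package: ratetrait
Title: Rate-Based Prediction of Life-History Trait Evolution from
    Gene-Branch Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Decomposes per-gene, per-branch molecular evolutionary rates
    on a species tree into branch effects, gene effects and gene-branch
    interactions; regresses life-history traits on the interactions with
    LASSO-penalised models to predict ancestral states and identify
    predictor genes; builds partial-correlation and minimum-BIC forest
    trait coevolution networks; and fits correlated-evolution Markov
    models for pairs of binary traits with maximum-likelihood and MCMC
    inference.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    glmnet,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
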