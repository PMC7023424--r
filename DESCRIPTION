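Package: goatQG
Title: Bayesian Genetic Parameters for Goat Kid Growth and Survival
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pedigree-based quantitative-genetic analysis of goat kid
    growth, conformation and survival under smallholder herd structures.
    Provides additive relationship matrices from pedigrees, a synthetic
    herd generator emulating a smallholder recording scheme, Gibbs
    samplers for bivariate repeatability-maternal animal models of body
    weight and conformation traits and for a right-censored log-normal
    accelerated failure time animal model of kid survival, and posterior
    summaries of heritability, repeatability and genetic correlations
    with highest posterior density intervals and convergence diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml,
    Matrix,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'pedigree.R'
    'reference.R'
    'config.R'
    'simulate.R'
    'records-io.R'
    'growth.R'
    'survival.R'
    'summaries.R'
    'descriptives.R'
    'goatQG-package.R'
    'recovery.R'
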