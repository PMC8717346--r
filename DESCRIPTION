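Package: songspace
Title: Acoustic Spaces, Song Dimorphism Metrics and Phylogenetic Mixed Models for Comparative Bioacoustics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for comparative analyses of male and female song structure
    across populations and species. Builds random-forest acoustic spaces
    (supervised sex classification with out-of-bag error; unsupervised
    proximity embeddings via classical and non-metric multidimensional
    scaling), computes 95% minimum-convex-polygon acoustic areas, per-song
    element diversity and three male-female song dimorphism metrics with
    balanced resampling, reduces song elaboration variables by principal
    component analysis, and fits Bayesian phylogenetic mixed models by a
    blocked Gibbs sampler with parameter-expanded variance priors, pMCMC,
    autocorrelation/effective-sample-size diagnostics and DIC-based model
    ranking. Includes a hierarchical synthetic-data generator (Brownian-motion
    species effects on a simulated tree, nested population/individual/song
    structure, planted sex-by-life-history interactions) so the whole pipeline
    is testable without field data, plus Blomberg's K for phylogenetic signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    MASS,
    ape,
    randomForest,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite,
    optparse
Config/testthat/edition: 3
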