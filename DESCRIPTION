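Package: lifecube
Title: Dimensionless Life-History Metrics and Comparative Macroevolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes Charnov's three dimensionless life-history metrics
    (lifetime reproductive effort, relative reproductive lifespan and relative
    offspring size) from species trait tables, and analyses their evolution on
    dated phylogenies: maximum-likelihood fitting of Brownian-motion,
    Ornstein-Uhlenbeck, Pagel's lambda and kappa trait models with AIC
    selection, permutation tests of phylogenetic signal, univariate and
    multivariate phylogenetic generalized least squares with evolutionary
    correlations and optional measurement error, Brownian ancestral-state
    reconstruction, clade-level ANOVA, and four-dimensional Gaussian
    kernel-density hypervolumes with Sorensen overlap. Includes a seeded
    synthetic-data generator (Yule trees, multivariate trait simulation,
    trait-database emulation with known ground truth) and an end-to-end
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
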