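Package: withinphylo
Title: Within- and Between-Species Trait Trends with Bayesian Phylogenetic Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Disentangles within-species (anagenetic) from between-species trait
    trends in fossil lineages using within-group-centered Bayesian phylogenetic
    generalized linear mixed models fitted by a conjugate blocked Gibbs sampler.
    Builds uncertainty-propagating replicate datasets from specimen tables
    (uniform age resampling, taxonomic randomization, stratified body-mass
    imputation) paired with posterior samples of non-ultrametric time-calibrated
    trees, and aggregates replicate-wise significance (pMCMC), phylogenetic
    heritability, marginal and conditional R-squared, DIC, and per-species
    within-time slopes. Includes a synthetic-data generator covering the
    canonical within/between evolutionary scenario grid.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
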