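Package: aflpsgs
Title: Spatial Genetic Structure, Diversity and Inbreeding from Dominant AFLP Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of dominant (presence/absence) AFLP marker data in
    spatially sampled populations. Provides Bayesian estimation of null-allele
    frequencies from dominant phenotypes with a moment-matched beta prior,
    gene diversity (Hj) and polymorphism statistics, moment FST estimators,
    pairwise multilocus kinship coefficients for dominant markers, distance-class
    spatial autocorrelograms with permutation envelopes and jackknife-over-loci
    errors, the Sp statistic of isolation-by-distance intensity, Mantel tests,
    an FST-outlier neutrality scan based on a simulated island-model null cloud,
    and hierarchical Bayesian estimation of individual inbreeding coefficients by
    Metropolis-within-Gibbs MCMC. Includes seeded synthetic-data generators with
    known truth (unstructured, island-model, pedigree pairs, inbred samples, and
    forward-time stepping-stone landscapes) and an end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    geosphere,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
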