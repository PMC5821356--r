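Package: demicabc
Title: Spatially Explicit Range-Expansion Simulation and ABC Inference for
    Microsatellite Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a demic range expansion over a lattice of square demes
    (forward-in-time stochastic logistic demography with stepping-stone
    migration, backward-in-time Wright-Fisher coalescent with single
    stepwise microsatellite mutation), reduces genotypes to six regression
    "pattern" statistics (diversity and F_ST clines against distance from
    the expansion origin), and infers six demo-genetic parameters by
    Approximate Bayesian Computation with local-linear regression
    adjustment. Includes estimator validation on pseudo-observed datasets,
    population-frequency PCA comparison, an EM admixture clustering with
    replicate alignment, and Evanno's Delta-K, so that both clines and
    clusters emerging from a single diffusion model can be examined.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
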