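Package: spatNb
Title: Effective Number of Breeders in Spatially Structured Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation of the effective number of breeders (Nb) from
    single-cohort microsatellite samples taken across a spatially
    structured population. Implements a bias-adjusted linkage
    disequilibrium (LD) Nb estimator with jackknife confidence intervals,
    a sibship dyad-frequency Nb estimator built on pairwise-likelihood
    full-sib reconstruction with a clutch-maternity prior, marker quality
    control (exact Hardy-Weinberg tests, null-allele EM, interlocus LD
    permutation tests), spatial-structure diagnostics (individual
    pairwise Moran's I autocorrelograms, spatial PCA, Weir-Cockerham
    FST, Nei's FIS), incremental buffer-window analyses, three
    metapopulation-Nb estimators, and a forward-time spatially explicit
    simulator with known pedigree truth for validating the estimators
    under isolation-by-distance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
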