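Package: refugia
Title: Demographic Inference and Glacial-Refugium Distribution Modeling for
    Disjunct Alpine Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing the Quaternary history of disjunctly
    distributed mountain plants from reduced-representation SNP data and
    gridded climate. Simulates two-population divergence scenarios
    (vicariance, old founder event, recent founder event) under a structured
    coalescent with migration epochs, builds folded two-dimensional joint
    site frequency spectra with missing-data filtering and hypergeometric
    down-projection, fits a registry of island demographic models by a
    multi-round perturbation protocol and ranks them by AIC and Akaike
    weights, converts scaled divergence estimates to absolute times by
    gamma sampling of substitution rates and generation times, computes
    per-population diversity descriptors (nucleotide diversity, private
    alleles) with Mann-Whitney comparisons, and implements a two-step
    delta-method paleoclimate downscaling feeding a refugium-augmented
    pseudo-absence GLM species distribution model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    generics,
    Rcpp,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
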