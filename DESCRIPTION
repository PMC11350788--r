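Package: nichecast
Title: Presence-Background Niche Models and Climate-Driven Threat Reclassification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for assessing how projected climate change
    alters species conservation status. Fits presence-background maximum-entropy
    (Gibbs) species distribution models with L1 regularization and logistic
    output, screens bioclimatic predictors by pairwise correlation and variance
    inflation, binarizes habitat suitability into four habitability classes with
    Fisher-Jenks natural breaks, computes geodesic range areas and projected
    range-loss fractions under future climate scenarios, and maps losses onto
    ordered IUCN-style threat categories, including geometry-based elevation
    rules for data-poor species with one to three records. Ships a virtual
    species simulator providing climate surfaces, scenario deltas and species
    with known niches, so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    geosphere
Config/testthat/edition: 3
RoxygenNote: 7.3.3
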