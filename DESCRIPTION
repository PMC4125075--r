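Package: phenosig
Title: Phenotypic Signatures from Unbalanced Bacterial Growth Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts wavelet-based phenotypic signatures from plate-reader
    growth curves measured during unbalanced (batch) growth and uses them to
    classify bacterial strains and growth conditions. Includes tools to
    compute specific growth rates, denoise curves with a db4 wavelet and a
    universal soft threshold, build time-period coefficient maps, select
    informative periods by the Davies-Bouldin index, and run leave-one-out
    misclassification analyses. Companion simulation modules quantify how
    cell-coupled (nutrient-consuming) input signals improve local parameter
    identifiability and regression-based network inference in random
    three-node models, and reverse-engineer a three-variable growth ODE from
    growth-rate data with a particle-swarm search over an equation-component
    library.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    jsonlite,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
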