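Package: recombkit
Title: Simulation and Genomic Prediction of Meiotic Recombination Rate
    Variation in Multi-Parent Crossing Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying meiotic recombination rate variation in
    double round-robin (DRR) crossing designs of inbred lines. Simulates
    recombinant inbred line (RIL) populations under a window-based
    recombination landscape with per-parent general (GRE) and per-cross
    specific (SRE) recombination effects; cleans genotypes and builds
    anchored linkage maps; estimates windowed recombination rates from
    Marey-map smoothing splines; decomposes cross-level rates into GRE and
    SRE by REML-fitted BLUP; and predicts recombination rates and GREs with
    GBLUP/RR-BLUP under fivefold and leave-parents-out cross-validation.
    Includes crossover counting with an outlier rule and a multi-population
    permutation-thresholded QTL scan of crossover counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
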