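Package: metablup
Title: Joint Genomic and Metagenomic Prediction with Multi-Kernel Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for partitioning phenotypic variance in livestock between
    host genetics and the rumen metagenome, and for predicting phenotypes from
    either or both data sources. Builds a VanRaden genomic relationship matrix,
    six metagenome relationship matrices from log relative abundances of
    metagenome-assembled gene (ORF) counts (two construction methods crossed
    with naive, heritability-weighted, and data-driven multi-population
    adjustments), and Hadamard genome-by-microbiome interaction kernels. Fits
    univariate animal models with up to three correlated random effects by
    average-information REML with EM fallback, reports variance ratios
    (heritability, microbiability, and their sums) with delta-method standard
    errors and AIC, and evaluates phenotypic prediction under stratified
    fourfold and leave-one-diet-out cross-validation using total animal merit
    accuracy, RMSE, and dispersion. Includes a synthetic-data generator with
    known ground truth emulating a multi-diet beef cattle feed efficiency
    study design, and an end-to-end workflow driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
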