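Package: cuscreen
Title: Pooled Barcode Fitness Screens for Copper-Dependent Respiratory
    Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for chemogenomic fitness screens of pooled,
    barcoded yeast deletion collections grown under respiratory conditions
    with and without copper supplementation. Provides a synthetic-data
    generator with known ground truth for competitively grown pools and
    plate-reader growth curves; log2 transformation and group-wise quantile
    normalization of tag intensities; per-strain Copper Response Scores
    with the maximum-absolute-difference tag selection rule; empirical-Bayes
    moderated t-statistics with Benjamini-Hochberg q-values; a
    respiration-deficient pool filter; per-replicate fold-change matrices
    with hierarchical clustering; hypergeometric Gene Ontology
    overrepresentation analysis; and growth-curve AUC and relative-growth
    statistics for isogenic dose-response experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    ape
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
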