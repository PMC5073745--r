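Package: kineticDE
Title: Per-Gene Interaction Models for Dye-Swap Time-Course Two-Colour
    Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical pipeline for early-response time-course two-colour
    microarray experiments laid out as a dye-switch design: per-gene
    additive versus time-by-treatment interaction linear models fitted by
    ordinary least squares, nested F-tests with Benjamini-Hochberg false
    discovery rate control, per-timepoint differential expression calls
    under Bonferroni familywise control, Venn partitioning and
    hypergeometric overlap statistics for gene sets, functional-bin
    over-representation analysis, hierarchical clustering of expression
    profiles, and the accompanying physiology statistics (chlorophyll
    quantification, exact Mann-Whitney rank-sum and Welch t tests). A
    seeded synthetic-data generator produces expression matrices obeying
    the model with known ground truth so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
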