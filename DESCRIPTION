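Package: hena
Title: Construction of a Heterogeneous Network Data Set for Alzheimer's Disease
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds a heterogeneous gene-level interaction network for
    Alzheimer's disease research from multi-omic inputs: cross-study
    rank-aggregated co-expression (Robust Rank Aggregation of Spearman
    correlations), exhaustive pairwise-SNP epistasis scans with genic and
    intergenic bin mapping and region-wise Bonferroni correction,
    brain-region expression Z-score aggregation, and integration into a
    typed, scored edge list with a 237-field node attribute table.
    Includes a seeded synthetic-data module with planted signals for
    end-to-end verification, and a disease-gene prioritization use case
    built on graph neighborhood features.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
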