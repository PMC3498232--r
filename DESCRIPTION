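Package: panicleHeat
Title: Time-Course Heat-Stress Transcriptome and Promoter Cis-Element
    Analysis for Rice Panicle
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for the classic single-channel microarray
    heat-stress workflow in rice panicle: quantile normalization with
    replicate quality control, detection-flag (P/A/M) filtering,
    per-time-point fold-change calling against an untreated control,
    heat-responsive gene definition, k-means co-expression clustering
    with temporal pattern labelling, hypergeometric category
    over-representation, IUPAC consensus scanning of -3000 bp promoters
    for cis-regulatory elements, motif enrichment and windowed motif
    co-occurrence statistics with Cytoscape-style network export, and
    2^(-ddCt) qPCR relative quantification. Includes synthetic-data
    generators with known ground truth for expression matrices, promoter
    databases and qPCR plates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    S4Vectors,
    limma,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
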