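Package: coresig
Title: Core Differential Expression Signatures via Two-Stage Gene Set Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a core differentially-expressed gene signature from
    case/control expression matrices: a three-stage probe filtering cascade
    (presence floor, coefficient-of-variation, sex-association), a from-scratch
    gene-set enrichment engine (signal-to-noise ranking, weighted
    Kolmogorov-Smirnov running-sum enrichment score, absolute-value pre-screen
    followed by classical enrichment, phenotype-permutation nominal p-values),
    gene-level up/down classification at a fixed score cutoff, and
    median-threshold selection of genes by the number of enriched pathways
    they drive. Includes a synthetic-data generator with planted ground truth,
    readers and writers for GCT/CLS/GMT/TSV/JSON, cosine hierarchical
    clustering for signature heat maps, and small assay quantifications
    (delta-delta-Ct relative quantification, Fura-2 F340/F380 calcium ratios,
    corrected total cell fluorescence).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    ape,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
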