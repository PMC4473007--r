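Package: islandscape
Title: SICER-Style Island Calling and Promoter Histone-Signal Analysis for
    ChIP-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Windowed summarization of aligned ChIP-Seq reads, Poisson
    background island (broad peak) calling with E-value control, two-condition
    peak comparison, peak-to-gene annotation with genomic-feature
    classification, meta-gene and TSS enrichment profiles stratified by
    expression level, and k-means clustering of promoter histone signal.
    Includes a synthetic-data generator that plants TSS-centred enrichment
    coupled to gene expression so every stage can be benchmarked against
    ground truth, and a single-config pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    ggplot2,
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
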