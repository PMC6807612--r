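Package: elncloop
Title: Enhancer lncRNAs and Chromatin Interaction Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide analysis of enhancer long non-coding RNAs
    (elncRNAs) and chromatin interactions. Calls active enhancers from
    GRO-seq peaks and elncRNAs from lncRNA/enhancer overlap, builds
    enhancer-promoter pairs from Hi-C contact lists with a
    distance-decay binomial significance model and Benjamini-Hochberg
    filtering, profiles lncRNA density and ChIP-seq peaks around
    chromatin loop anchors, clusters pairs on Z-normalized structuring
    factor signals with Pearson-correlation distance, and classifies
    lncRNAs by promoter versus gene-body G-quadruplex density. Includes
    a seeded synthetic-data generator emulating the statistical
    structure of the inputs so the full pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
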