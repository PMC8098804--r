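Package: dormantnc
Title: Regulatory Non-Coding RNA Analysis of Peach Bud Dormancy Release
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classification and expression analysis of regulatory non-coding
    RNAs across dormancy and flowering stages of peach floral buds.
    Implements small RNA locus classification by reference class, major RNA
    size and genomic origin (including heterochromatic siRNA calling and
    novel microRNA post-filters), a positional taxonomy for long non-coding
    RNAs with partner gene assignment, median-of-ratios normalization with
    pairwise differential expression under a fold-change/FDR contract,
    correlation-based co-expression modules with eigengenes and module-trait
    correlation, plant microRNA target site scoring with degradome peak
    categories, 24-nt phasiRNA (PHAS) locus detection with a trigger
    microRNA conjunction rule, interaction networks with hub scores, and QTL
    co-localization. A seeded synthetic data generator with planted ground
    truth makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    limma,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    Matrix,
    rtracklayer,
    stats,
    utils
Suggests:
    DESeq2,
    optparse,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
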