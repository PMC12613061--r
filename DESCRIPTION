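Package: regumirror
Title: Cross-Species Comparative Transcriptomics and YAP/TAZ-TEAD Target Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistics for comparing differential-expression signatures across
    datasets and species (hypergeometric overlap tests with Benjamini-Hochberg
    correction, Venn partitioning, direction concordance, Spearman correlation
    of shared fold changes, over-representation analysis over GMT catalogs with
    redundancy simplification, Fisher's exact tests, and ranked gene set
    enrichment analysis with a gene-permutation null), together with a
    ChIP-seq-based transcription-factor target-prediction funnel: blacklist
    filtering, promoter-window peak assignment, five-tier peak-score
    classification, cross-species YAP1+TEAD promoter-occupancy consensus,
    TEAD position-weight-matrix motif filtering, and intersection with
    consistently downregulated genes. A synthetic-data module generates every
    pipeline input with known ground truth so all stages are testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse
Config/testthat/edition: 3
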