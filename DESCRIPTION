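Package: ampliqc
Title: Benchmarking, Error Characterization and Filter Tuning for Amplicon
    Exome Variant Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Evaluates amplicon-based exome sequencing call sets against a
    gold-standard truth set restricted to high-confidence regions: VCF
    normalization (multiallelic splitting, indel left-alignment), exact
    allele-level benchmarking with sensitivity/FDR/F1, characterization of
    erroneous calls (multiallelic structure, indel length, low-depth false
    negatives, cross-sample recurrence), amplicon coverage and GC-dropout
    statistics, random read downsampling with coverage/variant-loss curve
    fits, and exhaustive-search derivation of multi-parameter quality
    filters that retain a target fraction of true positives while
    maximizing false-positive removal. A synthetic-cohort generator
    reproduces the error structure of flow-space semiconductor sequencing
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    methods,
    minpack.lm,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
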