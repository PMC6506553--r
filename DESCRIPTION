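Package: dvcscan
Title: Differential Variability and Correlation Analysis for Single-Cell Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genes whose expression variability and co-expression
    change between cell states in single-cell RNA-seq data. From a genes x
    cells count matrix with per-cell state labels, the pipeline normalizes
    counts (TMM scaling factors, log2 counts per million), detects
    co-expression modules in the earliest state by correlation-based Ward
    clustering with a dynamic (hybrid) tree cut, quantifies per-gene changes
    in variability (Levene test, Benjamini-Hochberg correction) and in mean
    within-module correlation between states, combines both into a state
    transition score (STS) used to rank candidate transition-regulator
    genes, and runs one-sided hypergeometric enrichment analyses including
    transcription-factor target sets built from regulatory-region interval
    overlap. A negative-binomial simulator with planted oscillatory modules
    provides ground-truth benchmarks for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    methods,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    ape,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    car,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
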