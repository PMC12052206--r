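Package: k27domains
Title: Broad H3K27me3 Domain Calling, Cross-Condition Comparison, and
    Dynamics Statistics for Spike-In Normalized Chromatin Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing broad repressive histone domains
    (H3K27me3 facultative heterochromatin) from fragment-level chromatin
    profiling data such as CUT&RUN, CUT&Tag and ChIP-seq.  Implements
    spike-in and depth normalized 100-bp binned coverage tracks with
    running-average smoothing, percentile-threshold domain calling with
    gap jumping and IgG enrichment filtering, disjoin-based decomposition
    of multi-condition domain sets into unique segments, classification of
    boundary changes (same, shrinking, spreading, new), k-means trajectory
    clustering, two-component Gaussian fitting of log2-ratio
    distributions with three-group partitioning, and hypergeometric /
    rank-sum overlap statistics with Benjamini-Hochberg correction.  A
    synthetic-data generator plants domains with known change scenarios so
    that every stage of the pipeline can be validated without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    ggplot2,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    GenomeInfoDb,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
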