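Package: epistate
Title: Spike-In Normalized Chromatin State Analysis of Hypomethylated Germ Cells
Version: 0.1.0
Authors@R:
    person("Epistate", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrative epigenomic analysis toolkit for spike-in normalized
    histone-modification ChIP-seq, ATAC-seq, bisulfite methylation and
    per-copy transposable-element expression. Implements spike-in
    normalization factors, pseudoreplicate-based reproducible peak
    retention, combinatorial chromatin-state classification of promoters
    and transposable elements, cross-cell-type state transition tables,
    threshold-based expression categorization and differential calls,
    TE-to-promoter proximity assignment with distance-resolved
    correlation, a from-scratch toroidal self-organizing map for
    multi-assay integration, the effect-size statistics used for
    reporting, and a ground-truth-bearing synthetic data generator that
    emulates the count structure of ultra-low-input native ChIP with a
    fixed-fraction exogenous spike-in.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
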