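Package: mrnorm
Title: Robust Multi-Reference Normalization of RNA-Seq Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Between-sample normalization of RNA-seq count matrices by
    pairwise robust regression against multiple reference samples.  Each
    target sample is aligned to every reference by least trimmed squares
    (LTS) regression on log2 counts, in a pure scaling (single-parameter)
    or power-law (double-parameter) form, and the pairwise intermediates
    are integrated under a two-factor least-absolute-deviations model
    solved by Tukey's median polish.  Includes normalization diagnostics
    (log-ratio density modes, skewness preservation, MA panels for
    spike-in controls), reference implementations of standard comparator
    normalizers (CPM, TPM, upper quartile, RLE, TMM, quantile), and a
    synthetic-data generator for benchmarking under known distortions.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    parallel,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma,
    DESeq2,
    jsonlite,
    optparse
Config/testthat/edition: 3
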