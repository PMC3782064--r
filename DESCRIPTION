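Package: cnvburden
Title: Rare Copy-Number Variant Burden and Region Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Case-control analysis of rare copy-number variants (CNVs) called
    from SNP arrays. Implements sample- and call-level quality-control
    cascades, segmental-duplication and frequency-based rare-set derivation,
    global burden testing of four statistics (CNV rate, carrier proportion,
    total and average CNV size) across type, frequency and size strata with
    one-sided case/control label-permutation p-values, per-sample gene-count
    burden with flanked gene spans, merging of overlapping rare CNVs into
    nonredundant CNV regions (CNVRs), and per-region carrier association by
    Fisher's exact test with empirical and min-p family-wise permutation
    correction. Includes a synthetic CNV dataset generator with planted
    effects for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
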