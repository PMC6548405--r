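Package: bivalr
Title: Quantitative Analysis of Bivalent Promoters from H3-Normalized ChIP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative chromatin-bivalency analysis of ChIP tag
    libraries: H3-normalized log2 promoter enrichment for H3K4me3 and
    H3K27me3 over 4 kb TSS windows, broad histone domain calling against
    local flanking background with Benjamini-Hochberg control, four-state
    chromatin classification (H3K4me3-only, H3K27me3-only, bivalent,
    neither) by enrichment threshold or peak-promoter overlap, state
    censuses and cross-condition transition/resolution statistics, average
    TSS metaprofiles, and ChIP-qPCR quantification (bound/unbound ratios,
    percent input, IgG subtraction). Includes a synthetic-data generator
    that simulates annotations, tag libraries, expression values and qPCR
    plates with known chromatin-state truth, so every pipeline stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    stats,
    utils,
    graphics
Suggests:
    Rsamtools,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
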