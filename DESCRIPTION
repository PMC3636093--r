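Package: breakscan
Title: Breakpoint Analysis for Gene Fusion Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers candidate gene fusions from the tell-tale breakpoints
    they leave in transcript-level and DNA copy-number data. Implements RNA
    breakpoint analysis (a "walking" Student's t-test over exon-resolution
    expression profiles with Bonferroni family-wise control), DNA breakpoint
    analysis (1-D fused-lasso segmentation of probe-level log2 copy-number
    ratios with permutation-calibrated penalty, copy-number smoothing of
    segment boundaries, and intragenic breakpoint calling), directional
    filtering against a cancer-gene list, paired-end RNA-seq fusion-partner
    nomination with chimeric junction-read rescue and reading-frame
    prediction, a supervised two-class expression signature with permutation
    FDR, and a seeded synthetic-data generator so every stage is testable
    end-to-end without external downloads.
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
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    Rsamtools,
    rtracklayer,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
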