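Package: astroid
Title: Transcript Reconstruction by Assembly of Effective Transcript Copies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs individual effective transcript copies from spliced
    paired-end RNA-seq alignments by solving a minimum-cost flow problem on a
    read flow network, and quantifies isoforms by counting effective copies
    (eTPM). Includes the splice-graph builder, a Weibull fragment/gap size
    model with a significance test for copy effectiveness, a lossless/lossy
    read-clustering compression of the flow network, MultiSplice penalties for
    unconfirmed multi-exon paths, an RNA-seq fragment simulator with ground
    truth, and evaluation utilities (transcript matching, sensitivity,
    precision, abundance correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    IRanges,
    S4Vectors,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    fitdistrplus
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
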