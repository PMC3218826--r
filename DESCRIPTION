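Package: mirsolid
Title: Small RNA-Seq Analysis of SOLiD Color-Space Reads for miRNA
    Discovery
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A small RNA deep-sequencing analysis pipeline for SOLiD
    di-base (color-space) reads: csfasta/qual parsing, color-space
    encoding and decoding, adapter trimming, seed-and-extend read
    matching under a color mismatch budget, hierarchical exclusive
    annotation of reads to non-coding RNA classes, miRNA counting with
    per-million normalization and abundance filtering, empirical-Bayes
    moderated-t differential expression, pre-miRNA arm profiling,
    exact color-space census for disambiguating near-identical miRNAs,
    canonical miRNA seed-site scanning with hypergeometric target
    enrichment, and a synthetic read generator with known truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
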