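Package: edbsa
Title: Bulked Segregant Analysis with the Euclidean Distance Statistic
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for bulked segregant analysis (BSA-seq) of two
    extreme-phenotype pools. Computes the per-site Euclidean distance (ED)
    between pooled base frequencies, raises it to the 4th power to suppress
    background noise, smooths it along each chromosome with local polynomial
    (LOESS) regression, calls trait-associated regions above a median + 3 SD
    threshold, and selects candidate SNPs by mutation frequency and raw ED.
    Includes per-sample genotype calling and site pre-filtering with
    stage-by-stage accounting, simplified genic annotation of candidate
    sites, hypergeometric term over-representation analysis with
    Benjamini-Hochberg correction, a fixed-effects genotype + age model for
    phenotype association, and a synthetic two-bulk simulator with planted
    QTL so the whole chain is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    ggplot2,
    rlang,
    vcfR,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
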