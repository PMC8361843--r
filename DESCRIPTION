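Package: trexr
Title: Tandem Repeat Expansion Detection and Genotyping from Long-Read
    Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-stage discovery and genotyping of tandem repeat (TR)
    expansions from noisy long-read genome alignments. The scan stage
    extracts large insertions from CIGAR strings and split alignments,
    screens them for tandem repeat content with a native wraparound
    dynamic-programming repeat finder, and delineates the reference TR
    locus without prior annotation. The genotype stage sizes the repeat in
    every read spanning a target locus, rescues clipped reads by
    re-anchoring a short reference flank inside the clipped sequence, and
    clusters per-read sizes into alleles with one-dimensional Gaussian
    mixtures selected by the Akaike information criterion. A seedable
    long-read simulator (heterozygous and multi-allelic expansions, mosaic
    allele mixtures, truth alignments with split records) and benchmarking
    utilities (truth-read classification, assembly flank-probe sizing,
    allele match criteria, Kolmogorov-Smirnov comparison of size
    distributions) make the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    mclust,
    methods,
    Rcpp,
    Rsamtools,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
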