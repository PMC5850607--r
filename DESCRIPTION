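Package: invsym
Title: Quantifying Symmetric Inversion Bias in Circular Prokaryotic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Alignment-based detection and quantification of chromosomal
    inversion symmetry around the replication origin-terminus axis of
    circular prokaryotic genomes. Computes maximal unique matches (MUMs)
    between genome pairs with a suffix-array finder or by parsing MUMmer
    output, scores X-type symmetry across the alignment plane, and derives
    the D statistic measuring how close the point of maximal symmetry lies
    to the ori-ter axis. Includes an inversion simulator that generates
    genome pairs diverged by random, symmetric, or quasi-symmetric
    inversions, ori-ter-linked genome-architecture features (rRNA distance
    to ori, COG class J enrichment, leading-strand gene fraction, octamer
    strand bias, GC skew), ori- and ter-centered territory analysis for
    multi-origin archaea, and distance-matched subsampling controls.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
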