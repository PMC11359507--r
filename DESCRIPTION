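Package: phamkit
Title: Phamily-Based Comparative Genomics for Bacteriophage Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative genomics of mosaic double-stranded DNA bacteriophage
    genomes. Reads annotated genomes (GenBank flat file, FASTA+GFF3, or bare
    FASTA with de novo ORF calling), assorts predicted proteins into
    "phamilies" (phams) by thresholded pairwise similarity with single-linkage
    closure, computes pairwise genome similarity metrics (gene content
    similarity, amino-acid identity of shared homologues, the proteomic
    equivalence quotient, and genome-wide nucleotide identity from
    seed-and-extend local alignments), clusters genomes into clusters and
    subclusters by similarity thresholds, quantifies concordance with a
    hierarchical viral taxonomy, renders Phamerator-style SVG comparison maps,
    and simulates mosaic genome datasets with planted pham, cluster, and
    taxonomy structure for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    Biostrings,
    IRanges,
    GenomicRanges,
    Matrix,
    igraph,
    Rcpp,
    jsonlite,
    yaml,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
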