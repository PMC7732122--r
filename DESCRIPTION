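Package: orphangene
Title: Gene-Space Construction and Concordant SNP Discovery for Orphan Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale toolkit for building genomic resources in species that
    lack a reference genome. Implements quality trimming of paired-end reads
    (Mott modified maximal-scoring-segment semantics), de novo de Bruijn
    transcript assembly with read-2 bubble resolution, construction of a
    non-redundant Unigene by translated homology search, iterative
    Unigene-guided assembly of genomic reads that recovers introns
    ("Genespace"), exon/intron structure inference by collinear HSP chaining,
    dual-caller concordant SNP discovery across a clone panel, and
    genetic-distance analysis (Prevosti distances, bootstrapped UPGMA, PCA,
    MAF spectrum). A seeded diploid genome and read simulator provides truth
    data so every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
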