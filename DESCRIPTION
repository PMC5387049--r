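Package: spliceCode
Title: Alternative mRNA Splicing Code Discovery from Genome Annotation
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Classifies exons of multi-transcript genes into seven splicing
    types and introns into the 36 classes defined by their flanking exon
    types, discovers paired splice donor/acceptor consensus sequences with a
    quaternary prefix/suffix tree pruned by probability and entropy
    percentiles, tests every consensus for enrichment or depletion in every
    intron class with Fisher's exact test, interprets IVS-style splice-site
    point mutations as shifts between enriched intron classes (including
    cryptic splice-site scanning), scores intron 3' ends against a U12
    branch-point position weight matrix, and quantifies within-gene
    co-occurrence of consensus ranks. Ships a synthetic genome generator
    with ground truth so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: AlternativeSplicing, Annotation, SequenceMatching, Software
RoxygenNote: 7.3.3
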