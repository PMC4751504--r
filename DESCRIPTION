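Package: ap2erf
Title: Genome-Wide Characterization of AP2/EREBP Transcription Factor Families
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for genome-wide identification and
    characterization of AP2/EREBP-like transcription factor superfamilies:
    position-specific scoring matrix (PSSM) construction from domain seed
    alignments with shuffle-calibrated E-values, candidate collection by
    profile scanning and similarity search, isoform collapsing and
    architecture-based subfamily classification (AP2, RAV, DREB/ERF),
    profile-anchored alignment with neighbor-joining phylogenies and
    bootstrap supports, anchor-based subgroup labelling, tandem and
    segmental duplication detection under intervening-gene and
    similarity/coverage criteria, synteny-based ortholog mapping,
    stress differential-expression calling with a SAM-style permutation
    FDR, and duplicate-pair expression-divergence classification.
    Includes a synthetic-genome generator with planted ground truth so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, Phylogenetics, GeneExpression, DifferentialExpression,
    SequenceMatching, Annotation
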