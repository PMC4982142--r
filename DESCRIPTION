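Package: dopseg
Title: Target-Region Detection from DOP-PCR Amplified Chromosome-Specific
    Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies genomic regions present on flow-sorted or
    microdissected chromosomes from DOP-PCR amplified sequencing data.
    Provides dual-genome contamination filtering by mapping quality,
    collapsing of reads into DOP-positions, segmentation of inter-position
    pairwise distances by circular binary segmentation, target-region and
    putative-deletion calling, gene completeness annotation, and variant
    density / heterozygosity accounting, together with a synthetic
    experiment simulator so the whole pipeline is testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    methods,
    IRanges,
    S4Vectors,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
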