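Package: TyProfiler
Title: Repeat-Family ChIP-seq Metaprofiling and Ty1 Retromobility Assay
    Statistics
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying transcriptional control of the Saccharomyces
    cerevisiae Ty1 LTR retrotransposon family. Simulates toy genomes carrying
    sequence-identical full-length elements plus solo-LTR (delta) copies,
    ChIP fragment sets with realistic multimapping ambiguity, and
    colony-count tables for retromobility assays. Processes fragment
    alignments into normalized per-base occupancy (duplicate removal, random
    multimapper assignment, fragment pileup, untagged-control
    normalization), builds element-anchored metaprofiles (per-base flanks
    plus 100 length-scaled body bins) averaged over all family copies, and
    quantifies dual-promoter occupancy balance between the Ty1 (+238) and
    Ty1i (+1000) transcription start sites. Also implements retromobility
    frequency estimation with zero-event upper limits and semi-quantitative
    RT-PCR / densitometry fold arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
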