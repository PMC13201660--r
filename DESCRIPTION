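Package: riboslicer
Title: Quantification of Ribosomal RNA Precursors from Long-Read Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing long-read (nanopore) alignments against a
    single 47S/45SN1 pre-rRNA reference. Reads are assigned to literature
    based processing intermediates by maximal minimal-reciprocal-overlap,
    embedded in a two-dimensional start/end intensity matrix for unsupervised
    hub detection, and used to call cleavage sites by a per-template
    mean-plus-2SD rule with replicate consensus. Per-base modification
    probabilities (SAM MM/ML tags) yield pseudouridine stoichiometry per
    site and per precursor, complemented by U-to-C mismatch ratios and
    z-normalised raw-signal window summaries. A deterministic synthetic read
    generator with planted template proportions, boundary jitter,
    exonucleolytic trails, deletions and modification stoichiometries makes
    the whole pipeline testable without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    igraph,
    ggplot2
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
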