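Package: gapsmith
Title: Assembly Gap Closing, Optical-Map Validation, and Annotation Census Tools
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale toolkit for revising draft genome assemblies of
    large repeat-rich plant genomes. Discovers and classifies N-run gaps
    (10/100/1000-N placeholders versus sized gaps), validates and corrects
    super-scaffold placement and orientation against nick-site optical maps
    with an ordered-map dynamic-programming aligner and permutation
    significance, closes gaps by splicing in long-read contig sequence
    anchored on both flanks, collapses duplication artifacts at tandem
    repeats, and maintains coordinate lift-over through every edit. Also
    grades gene models into high-confidence/low-confidence/repeat classes
    from BLAST tabular evidence, classifies small-RNA reads (hc-siRNAs,
    tRNA-derived fragments, polycistronic pre-miRNA clusters), and computes
    per-chromosome census and difference tables with parts-versus-totals
    validation. A deterministic synthetic-data generator (genomes, gapped
    drafts with planted errors, simulated contigs and optical maps) makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
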