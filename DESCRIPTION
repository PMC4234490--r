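Package: uplift
Title: Genome Assembly Upgrade Toolkit: Map-Guided Scaffold Curation,
    Pseudomolecule Anchoring and Release Bookkeeping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for upgrading a draft genome assembly into a
    chromosome-scale release using genetic-map and map-placement evidence:
    genotype calling and marker filtering for a biparental mapping
    population, detection and splitting of chimeric scaffolds at
    consensus breakpoints, tiling of scaffolds into pseudomolecules,
    recruitment of legacy-assembly segments, flank-based gap patching,
    gene identifier carry-over and minting with a stride/overflow scheme,
    annotation consolidation, and synteny block detection with 1:1 quota
    filtering for whole-genome-duplication analysis. Every pipeline
    edit is recorded in a replayable edit log from which AGP files and
    UCSC liftOver chains are derived. A synthetic-data generator
    produces a truth genome and derives all pipeline inputs from it so
    each stage can be exercised and scored without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
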