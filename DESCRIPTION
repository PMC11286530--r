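Package: carna
Title: Landscape Analysis of RNA-Chromatin Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of RNA-chromatin contact data of the iMARGI/GRID-seq family.
    Reads RNA-DNA contact pairs, gene annotation and chromatin signal tracks;
    assigns each contact's RNA end to a source gene and RNA class with a
    small-ncRNA-aware priority rule; classifies contacts as cis
    (intra-chromosomal) or trans (inter-chromosomal); summarises the class-level
    interaction landscape; calls trans-acting RNAs by a dual contact-count and
    trans-fraction threshold; exports per-RNA genome-wide interaction maps; and
    clusters contact regions by chromatin-mark enrichment. Includes a
    truth-known synthetic-data generator so every stage is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
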