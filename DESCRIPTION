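Package: spyclip
Title: Crosslink-Site Cluster Analysis for UMI-Tagged CLIP Sequencing Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for covalent-purification CLIP (SpyCLIP) libraries:
    UMI extraction and PCR-duplicate collapsing, 3' adapter trimming, insert-length
    filtering, crosslink-site cluster calling from read 5' starts, RPM quantification
    and input-normalised fold-enrichment calls of RBP-specific clusters, genomic
    element annotation with RBP-appropriate category precedence, pentamer z-score
    motif enrichment against annotation-matched random background, crosslink-motif
    positional profiles, mature-miRNA quantification with 3'-templated end variants,
    successive 7-mer miRNA target scanning with seed-complement density, HAR
    (harringtonine) enrichment calls, and length-normalised metagene profiles.
    Includes a synthetic-data generator with a complete ground-truth ledger so every
    stage is verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    stats,
    tools,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
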