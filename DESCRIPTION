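Package: adenoloop
Title: Dual-Genome ChIA-PET Analysis of an Episomal Adenoviral Vector
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for chromatin-interaction (ChIA-PET) data on a
    combined host + adenoviral-vector reference. Classifies paired-end tags
    (PETs) by genome of origin, clusters them into interaction loops, builds
    binned contact matrices with Knight-Ruiz balancing, segments the vector
    contact map into structural blocks by insulation score, calls host TADs
    and A/B compartments with stability metrics, maps vector-host loops to
    associated host genes with chromatin-state composition, and compares
    associated-gene expression between conditions. A seeded synthetic-data
    generator with planted ground truth emulates every input so the whole
    pipeline is testable end to end at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
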