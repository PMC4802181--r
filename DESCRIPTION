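Package: nbconform
Title: Nuclear Body-Genome Conformation Analysis Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline linking nuclear bodies (Cajal bodies in
    particular) to genome conformation and RNA processing. Implements
    4C-seq contact profiling (read preprocessing, 10 kb binning, running
    window smoothing, contact-region calling), permutation enrichment of
    gene classes near contact regions, high-content DNA FISH spot
    co-localization analysis with CB-dependent/independent classification,
    a geometric null model for nuclear body-chromosome territory
    association, small-RNA differential expression by a two-control
    concordance rule, and splice-junction noise quantification. Seeded
    synthetic-data generators with planted ground truth exercise every
    stage end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    EBImage,
    jsonlite,
    withr,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
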