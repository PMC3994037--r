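Package: restcobind
Title: Co-Binding Classification and Expression Integration for the Rest
    Repressor Complex in Pluripotent Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for ChIP-seq, TSS-seq and mRNA-seq data
    on the Rest (NRSF) repressor complex in two pluripotent cell states
    (embryonic stem and epiblast stem cells). Classifies Rest binding sites by
    Sin3A/Lsd1 co-occupancy (R+/S+/L+ through R+/S-/L-), compares site sets
    across cell states, associates sites with protein-coding genes and lncRNAs
    through a 50 kb 5'-end rule, clusters TSS tags into 500-base transcription
    start clusters and flags novel intergenic lncRNA promoters, profiles
    input-normalized chromatin signal around sites, scores evolutionary
    conservation, and selects knock-down responsive target genes by a
    fold-change rule. Includes a seeded synthetic-data generator (Poisson tag
    model with planted co-binding, cell-specificity and induction structure)
    and a minimal local-Poisson peak scorer so the whole pipeline is testable
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
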