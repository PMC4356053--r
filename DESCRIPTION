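Package: senesceq
Title: Senescence-Associated DNA Methylation and Nuclear Organization Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative analysis toolkit for replicative-senescence
    epigenomics. Calls differentially methylated regions (DMRs) from
    methyl-capture fragment coverage with a local-Poisson enrichment model run
    in both signal/control orientations, computes RPKM-normalized signal
    metaprofiles around anchor sites and lamina-associated domain (LAD)
    borders, quantifies enrichment of DMRs in LADs and histone-mark
    territories against size-matched random-region nulls, associates DMRs with
    differentially expressed genes via a binomial projection test, performs
    transcription-factor motif enrichment with dynamic-programming score
    calibration and a resampled-region null, and quantifies telomere Q-FISH
    images (nucleus segmentation, three-zone partition, spot detection,
    intensity length proxy). A synthetic-data module generates a toy genome
    with planted truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    EBImage,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
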