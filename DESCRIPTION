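Package: srnaclean
Title: Contaminant-Aware Analysis of Small RNA Sequencing from Low-Biomass Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying and removing reagent-derived contaminant
    small RNAs from sequencing data of low-biomass samples such as blood
    plasma. Implements adapter trimming, quality filtering and read
    collapsing; host/non-host read attribution with shuffled-decoy
    specificity control and cross-mapping correction; identification of
    extraction-column contaminants from negative-control libraries and a
    primer-based matching rule; spike-in based absolute quantification;
    qPCR second-derivative Cq calling and standard-curve quantification;
    a multi-criteria cascade nominating bona fide exogenous small RNA
    candidates; and titration-based determination of minimal safe input
    volumes. A synthetic-data module simulates plasma, mock-extraction,
    column-eluate and water libraries plus qPCR amplification curves so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
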