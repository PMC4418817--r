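Package: riboscout
Title: Riboswitch-Guided Discovery of Bacterial Riboflavin Transporters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale comparative-genomics pipeline for locating
    candidate riboflavin transporter genes through the FMN riboswitch.
    Predicts transcriptional units from gene order and intergenic
    distance, scans upstream regions with a position-wise log-odds
    profile of the FMN riboswitch under a calibrated bit-score cutoff,
    assigns transporter family membership by prototype-anchored local
    alignment with identity and coverage thresholds (bi-directional best
    hits and Markov clustering of the similarity graph), classifies
    genomes by co-occurrence of transporters with the riboflavin
    biosynthetic pathway, and draws a neighbor-joining phylogeny for
    display of the distribution. A synthetic-cohort generator plants
    riboswitches, transporter orthologs and pathway markers with known
    ground truth so every stage is testable end to end without external
    genome downloads.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
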