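Package: tpsurvey
Title: Genome-Wide Survey of the Terpene Synthase Gene Family
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide surveys of the plant terpene
    synthase (TPS) gene family. Identifies family members by dual-domain
    profile hidden Markov model searches (N-terminal PF01397-like and
    C-terminal PF03936-like domains) supplemented by protein homology search,
    tabulates domain architectures and domain-loss statistics, assigns
    subfamilies (TPS-a through TPS-h) by neighbor-joining phylogenies on JTT
    distances with reference anchoring, classifies expansion mechanisms
    (tandem duplication, segmental duplication via collinear anchor chaining,
    and mobile-element association), calls tissue-preferred expression and
    duplicate-pair expression divergence from count matrices, estimates
    pairwise Ka/Ks by the Nei-Gojobori method, screens isoprenyl diphosphate
    synthases for the partial C-terminal domain motif shared with TPSs, and
    applies coverage/identity rules to flag horizontal gene transfer
    candidates. Ships a fully labeled synthetic-data generator so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    phangorn,
    jsonlite,
    stats,
    utils,
    methods,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
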