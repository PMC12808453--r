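Package: HAStyper
Title: Comparative Genomics of Heme A Synthase Family Types
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classification and comparative-genomic analysis of the heme a
    synthase (HAS, Cox15/CtaA) family of integral membrane enzymes. Provides
    a seeded synthetic-data generator emulating the family's transmembrane
    architectures and conserved-motif statistics, global/local pairwise
    alignment with identity-based homology gating, hit filtering and Markov
    clustering, a Kyte-Doolittle transmembrane topology predictor with sided
    loop extraction, a cysteine-pair/TM-count/reference-identity type
    classifier with motif conservation tables, gene-neighborhood synteny and
    taxonomic distribution matrices, and phylogeny-side verification
    (minimal-ancestor-deviation rooting, monophyly tests, minimum-transition
    counting).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ape,
    igraph,
    Biostrings,
    IRanges,
    S4Vectors,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    phangorn,
    rtracklayer,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Phylogenetics, Clustering, Alignment, ComparativeGenomics
RoxygenNote: 7.3.3
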