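Package: miRcascade
Title: Small RNA Sequencing Analysis of Oxidative Stress-Responsive Plant MicroRNAs
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for small RNA sequencing analysis in plants:
    adapter trimming and tag collapsing, an ordered annotation cascade
    (structured non-coding RNA classes, perfect genome mapping, known miRNAs,
    exon/intron sense/antisense), novel miRNA discovery from hairpin secondary
    structure and minimum free energy, exact Audic-Claverie differential
    expression between two libraries with TPM normalisation, plant miRNA target
    prediction under Allen complementarity scoring and Schwab positional rules,
    RACE-style cleavage-site validation, GO over-representation, and
    construction of a miRNA-target regulatory network merged with
    protein-protein interactions. Includes a synthetic-data generator that
    plants miRNA hairpins, non-coding RNAs and target sites into a toy genome
    with known ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
biocViews: Sequencing, SmallRNA, DifferentialExpression, Network, GeneTarget
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
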