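Package: quiescreen
Title: Integrative Multi-Omics Screening for Epigenetically Silenced Genes
    in Genetically Quiescent Tumors
Version: 0.1.0
Authors@R:
    person("quiescreen", "developers", email = "quiescreen@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for integrative screens of rare tumors that
    are copy-number and mutation quiescent but epigenetically altered.
    Provides copy-number segmentation of marker-level log2-ratio tracks with
    quiescence summaries, somatic variant filter cascades with RNA-seq
    expression verification and binomial recurrence testing, two-group
    differential expression (SAM statistic with permutation q-values),
    gene-set enrichment with phenotype permutation, 450K-style
    methylation/expression integration with promoter-hypermethylation
    candidate selection, bisulfite peak-ratio methylation calls, and
    comparative-Ct qPCR relative quantitation. A synthetic cohort generator
    emulates the statistical structure of a small tumor cohort against a
    large comparator cohort so every stage is testable without
    controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    ape,
    IRanges,
    S4Vectors
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
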