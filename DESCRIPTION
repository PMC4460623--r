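Package: omicsdriver
Title: Integrative Network-Based Key Driver Discovery from Matched
    Tumor/Normal Multi-Omics Data
Version: 0.1.0
Authors@R:
    person("omicsdriver", "developers", email = "omicsdriver@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for identifying key driver genes,
    miRNAs and somatic mutation candidates from matched tumor/normal
    cohorts. Differential features are called by a two-of-three vote over
    a SAM-type permutation statistic, an empirical-Bayes moderated t-test
    and AUC-ROC. Co-expression modules are built from topological overlap
    and refined into directed gene regulatory networks by sparse-candidate
    hill climbing under the BDe score with curated and motif-scan priors,
    then pruned against promoter-methylation anti-correlation. miRNA-mRNA
    and TF-miRNA networks are assembled with hypergeometric filtering, key
    drivers are extracted as exact minimum dominating sets, somatic
    variants are tested for genomic proximity to dysregulated features by
    chromosome-preserving permutation, and driver sets are annotated by
    over-representation and druggability analysis. A synthetic-cohort
    generator with planted ground truth provides a fully offline test
    surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
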