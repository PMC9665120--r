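Package: epihybrid
Title: Methylation Inheritance Analysis for Methylation-Sensitive GBS Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of DNA-methylation inheritance in natural hybrids from
    methylation-sensitive genotyping-by-sequencing (msGBS) read-count
    matrices. Provides counts-per-million normalization with group-occupancy
    locus filtering, an exact conditional negative-binomial test for
    differentially methylated cytosines (DMCs) with Benjamini-Hochberg FDR
    control, classification of hybrid methylation at DMCs as additive,
    overdominant or underdominant relative to the parental species, promoter
    / gene-body / intergenic context annotation, genome-methylome distance
    analyses (Bray-Curtis and Euclidean distances, classical MDS, Mantel
    test, and a pairwise mixed model with crossed individual random
    effects), and a negative-binomial simulator of msGBS experiments with
    known truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    lme4,
    ape,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    optparse
Config/testthat/edition: 3
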