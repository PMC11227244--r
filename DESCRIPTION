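Package: phagetrack
Title: Phage Engraftment Tracking in Fecal Microbiota Transplantation Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for gut phageome analysis in fecal microbiota
    transplantation (FMT) trials: screening of assembled contigs into
    uncultivated virus genomes (UViGs), fragment-based average nucleotide
    identity (ANI) and alignment fraction (AF) estimation, greedy centroid
    clustering into viral operational taxonomic units (vOTUs), clone-level
    tracking of donor phages into recipients, gene-catalog CPM abundance
    profiles, donor engraftment efficacy, phageome origin partitions, and
    longitudinal diversity and stability statistics. Includes a synthetic
    FMT-cohort generator with ground truth for validating every pipeline
    stage without access to raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    vegan,
    lme4,
    lmerTest,
    emmeans,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
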