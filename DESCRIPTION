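Package: famscan
Title: Genome-Wide Transcription Factor Family Characterization and
    Salt-Stress Candidate Screening
Version: 0.1.0
Authors@R:
    person("famscan", "developers", email = "famscan@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide characterization of
    basic helix-loop-helix (bHLH) transcription-factor gene families and
    screening of salt-stress response candidates.  Provides a
    position-specific scoring model for detecting the 79-column bHLH
    domain in proteome-scale protein sets, residue-rule prediction of
    DNA-binding class (G-box, E-box, non-E-box), neighbor-joining
    phylogeny with bootstrap support and reference-based subfamily
    assignment, exon/intron structure statistics from GFF3 gene models,
    IUPAC cis-regulatory element scanning of promoters, expression
    filtering/clustering/fold-change screening with GO-based candidate
    union, and qPCR 2^-ddCt statistics with one-way ANOVA and Duncan's
    multiple range test.  Ships a seeded synthetic-data generator that
    produces complete genome+transcriptome+qPCR fixture bundles with
    ground-truth labels for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    rtracklayer,
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
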