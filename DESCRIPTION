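Package: badger
Title: eQTL-Based Detection and Correction of Sample Mix-Ups Between
    Expression and Genotyping Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identity quality control for studies that profile the same
    individuals on expression and genotyping arrays.  Expression levels at
    strong cis-eQTLs (including cis-eQTL artefacts caused by SNPs under
    expression probes) are used to predict B-allele counts via per-genotype
    kernel density estimates; a score matrix of squared differences between
    predicted and observed counts is ranked to confirm intended
    expression-genotype pairings, and rank evidence is turned into concrete
    plating-error hypotheses (swaps, cycles, slippage and systematic plate
    transforms) via bipartite-graph resolution.  Includes a synthetic-cohort
    simulator with planted errors, tumour loss-of-heterozygosity, population
    structure and relatives; sex-based plate-layout design mathematics; and
    expression-array quality metrics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
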