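Package: hlafine
Title: Residue-Level HLA Association Scanning and Binding-Pocket Electrostatics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fine-mapping of HLA class II case-control associations at
    amino-acid resolution. Translates four-digit HLA-DRB1 diplotypes into
    per-residue amino-acid genotypes from an exon-2 alignment, runs stepwise
    conditional likelihood-ratio scans under allele-dosage and genotype
    codings, and computes carrier- and allele-level contingency statistics
    (Woolf odds ratios with optional Haldane correction, chi-square or Fisher
    tests, Bonferroni adjustment). Includes a Hardy-Weinberg case-control
    cohort simulator with residue-driven logistic risk, and a desk-scale
    finite-difference linearized Poisson-Boltzmann solver with Debye-Hueckel
    boundary conditions, Stern-layer ion exclusion and two-stage grid
    focusing, for classifying the electrostatic sign of peptide-binding
    pockets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
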