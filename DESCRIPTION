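Package: gxescan
Title: Set-Based Mixed-Effects Score Tests of Gene-Environment Interaction
    with Genetically Predicted Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Genome-wide set-based testing of gene-environment interaction in
    case-control studies. For each gene, eQTL dosages are collapsed into a
    genetically predicted expression level using external elastic-net weights
    (PredictDB-style), and the interaction between the gene and an exposure
    (continuous or binary) on disease risk is tested with a mixed-effects
    score test: a 1-df fixed (burden) component for predicted-expression-by-
    exposure interaction, a variance-component (SKAT-type) score test for
    residual SNP-by-exposure effects, and a data-adaptive combination of the
    two component p-values. Includes tiered imputation-quality filtering,
    allele harmonization, genome-wide scanning with Benjamini-Hochberg FDR
    control, sequential conditional SNP-level follow-up, exposure-stratified
    expression associations, and a synthetic cohort generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
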