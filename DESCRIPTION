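Package: mucosaSMI
Title: Spatial Single-Cell Multiomics Analysis of Colonic Mucosa
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for imaging-based spatial molecular imaging
    (SMI) of sigmoid-colon biopsies across inflammatory bowel disease (IBD),
    Parkinson's disease (PD) and neurologically healthy control (NHC) cohorts.
    Provides per-cell quality control for RNA and protein panels (negative-probe
    rules, iterative Grubbs area-outlier testing), posterior-gated supervised
    cell-type annotation from reference expression profiles, disease-vs-control
    cell-type composition and differential-expression statistics with
    Benjamini-Yekutieli adjustment, gene-set over-representation analysis,
    marker-stratified 25 um neighborhood ligand-receptor interaction analysis
    with a within-FOV label-permutation null, fluid-biomarker regressions, and a
    synthetic-cohort generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
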