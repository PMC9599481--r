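Package: liponet
Title: Integrated Quantitative Lipidomics-Proteomics Analysis of Dyslipidemic Serum
Version: 0.1.0
Authors@R:
    person("liponet", "developers", email = "liponet@example.org", role = c("aut", "cre"))
Description: Pipeline for integrated targeted lipidomics and proteomics
    concentration tables from dyslipidemia cohorts: quality-control filtering
    and half-minimum imputation, lipid species name parsing with fatty-acyl
    saturation categorization (odd-chain, SFA/MUFA, DUFA, PUFA), nonparametric
    differential abundance against a normolipidemic reference with
    Benjamini-Hochberg FDR, dual-filtered lipid-protein Pearson correlation
    networks with hub ranking and local hypergeometric over-representation
    analysis, and a bootstrap-forest-screened greedy "leading predictor" search
    over small multilayer perceptrons with Gaussian hidden nodes. Includes a
    synthetic cohort generator emulating the statistical structure of serum
    lipoprotein data for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    igraph
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
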