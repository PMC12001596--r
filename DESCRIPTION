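Package: pathlmm
Title: Pathway-Level Differential Analysis for Longitudinal Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Differential analysis of metabolic pathways from longitudinal
    metabolomic quantifications. Each pathway's metabolite sub-matrix is
    summarised by principal-component scores (global PCA, or per-time-block
    partial PCA in the spirit of Multiple Factor Analysis); a Gaussian linear
    mixed model with a random individual intercept is fitted to every score
    column, fixed effects (time, condition) are tested by likelihood-ratio
    tests, component p-values are aggregated per pathway with Simes'
    procedure and corrected across pathways by Benjamini-Hochberg. Also
    provides an over-representation analysis comparator, a semi-synthetic
    simulation framework (null transforms, effect injection, pathway-size
    designs), a fully synthetic base-data generator and an evaluation
    harness for type-I error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
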