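Package: dietshift
Title: Longitudinal Diet-Microbiome-Immune Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a single-arm pre/post anti-inflammatory
    diet intervention in inflammatory bowel disease: scoring of 24-hour food
    queries into diet categories, mixed-effect random forest models of
    repeated microbiome samples fitted by alternating (EM-style)
    optimization, permutation-importance (PIMP) significance testing,
    repeated-measures correlation of foods with species, alpha/beta
    diversity with PERMANOVA, cytokine-food regressions, and Monte-Carlo
    power calculations for the paired Wilcoxon signed-rank test. Includes a
    synthetic longitudinal cohort generator with known ground-truth effects
    so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    vegan,
    permute,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
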