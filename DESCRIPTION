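Package: vusclassifyr
Title: Functional Classification of CDKN2A Variants from Cell Proliferation Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for benchmark-anchored functional classification of
    CDKN2A (p16INK4A) protein variants assayed by in vitro cell proliferation.
    Normalizes replicate cell counts against empty-vector controls, calibrates
    classification thresholds from benchmark pathogenic and benign variants
    (Z-score confidence limits, ROC AUC, midpoint or Youden cutoff), assigns
    four-tier functional categories, forms cross-cell-line consensus calls,
    applies ACMG PS3-based reclassification of variants of uncertain
    significance, compares cell-cycle phase fractions between functional
    groups, and recomputes carrier prevalence in pancreatic cancer cohorts
    with modified Wald (Agresti-Coull) binomial confidence intervals. Includes
    a synthetic-data generator and a constraint-satisfying fixture so the full
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
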