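Package: crcpanel
Title: Multi-Scale Copy-Number, Expression and Drug-Sensitivity Analysis of
    Colorectal Cancer Cell-Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrative analysis of colorectal cancer cell-line
    panels: four-parameter logistic dose-response fitting with censored IC50s
    and per-drug sensitivity classification; CBS-style segmentation of
    marker-level aCGH log2 ratios with permutation split testing; recurrent
    gain/loss region detection across samples; quantile normalisation,
    detection filtering, SAM-style permutation differential expression and
    Mann-Whitney tests against sensitivity classes; stepwise copy-number by
    expression integration into a candidate-biomarker ledger; and two-colour
    FISH amplification-ratio scoring for tissue microarrays.  A synthetic
    panel generator with planted ground truth makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    limma,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
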