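Package: tsgnet
Title: Multi-Omics Differential Coexpression Analysis of Tumor Suppressor Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch-robust rank-based differential expression, differential
    coexpression screening with Fisher z-difference tests, combination of
    dependent p-values by the Empirical Brown method, copy-number cis/trans
    linear scans of methylation and expression, gene-set over-representation
    analysis, and integration of enrichment evidence across omics layers for
    tumor suppressor gene (TSG) characterisation and prediction. Includes a
    synthetic multi-omics data generator with known ground truth so every
    stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
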