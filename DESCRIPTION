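Package: tmbpanel
Title: Panel-Based Tumor Mutational Burden Estimation and Its Accuracy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes whole-exome and in-silico panel-based tumor mutational
    burden (TMB) from MAF-style somatic mutation tables, dichotomizes samples
    at per-cancer-type quantile cutpoints, and contrasts Pearson correlation
    (R^2) with dichotomous accuracy, false positive/negative rates and
    positive/negative percentage agreement. Includes outlier-robustness
    analyses (successive removal of top-ranked-TMB cases, TMB-subgroup
    correlations), a random virtual-panel experiment that searches for the
    minimal gene count per cancer type reaching a target mean accuracy, and
    a seeded synthetic-cohort generator so the whole pipeline runs without
    any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
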