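Package: sncfam
Title: Family-Level Differential Abundance Analysis of Small Non-Coding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Aggregates unique small non-coding RNA (sncRNA) species into their
    parental-RNA families (tsRNA, rsRNA, ysRNA, ...) and tests family-level
    differential abundance. Provides a covariate-adjusted linear model on
    log10-transformed reads-per-million (RPM) for multi-sample group or
    continuous-phenotype comparisons, and an exact Wilcoxon signed-rank test
    for paired "1-on-1" comparisons with positive/negative rank-sum direction
    calls. Includes RPM normalisation and filtering of species-level
    quantification tables, family-size constraints with Bonferroni correction,
    a resampling robustness evaluator, cross-cohort concordance summaries,
    parental-RNA coverage profiles, and a synthetic cohort generator for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
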