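Package: episigr
Title: Blood DNA Methylation Episignature Discovery and Variant Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy workflow for deriving case/control DNA-methylation
    episignatures from Illumina-style beta-value matrices and classifying
    unseen samples. Covers probe quality filters, reference-based blood
    cell-type deconvolution, epigenetic-clock age estimation and age
    acceleration, covariate-adjusted differential methylation with
    empirical-Bayes variance moderation and dual FDR/effect-size thresholds,
    hypergeometric island/shore and gene-set enrichment, correlation pruning,
    and a probability-calibrated support vector machine scorer. Includes a
    synthetic-cohort generator so the full pipeline is testable without
    protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    fgsea,
    ggplot2,
    generics,
    jsonlite,
    limma,
    purrr,
    quadprog,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
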