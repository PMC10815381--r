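Package: csfmr
Title: Proteome-Wide cis-Mendelian Randomization Screening of CSF Protein
    Effects on Cognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for proteome-wide two-sample cis-Mendelian
    randomization screens of cerebrospinal-fluid protein levels against
    cognitive and other outcomes from GWAS summary statistics: cis-pQTL
    instrument selection with greedy LD clumping, effect-allele
    harmonization with palindromic-variant handling, Wald-ratio and
    random-effects inverse-variance-weighted causal estimation with
    Cochran's Q and I-squared heterogeneity statistics, weighted-median
    sensitivity analysis, Benjamini-Hochberg false-discovery-rate control,
    single-causal-variant Bayesian colocalization via Wakefield approximate
    Bayes factors, and a phenome-wide logistic-regression scan. A
    linkage-disequilibrium-structured synthetic GWAS generator with known
    causal architecture makes every stage testable end to end without
    access to controlled GWAS data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
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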