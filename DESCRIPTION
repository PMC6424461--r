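Package: multihitr
Title: Multi-Combination Multi-Hit Models of Carcinogenesis from Somatic
    Mutation Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the average number of carcinogenic mutations (hits)
    required for carcinogenesis from the cohort distribution of per-tumor
    somatic mutation counts. Implements closed-form probabilities that the
    m-th accumulated somatic mutation completes one of k alternative
    combinations of h carcinogenic mutations, fits h and k to observed
    tumor mutation burden distributions by RMSD minimization, supports
    two-component mixtures of hit numbers, percentile-bootstrap confidence
    intervals, subsample-stability and genome-target-size sensitivity
    analyses, MAF ingestion for per-sample mutation counting, synthetic
    cohort simulation by inverse-CDF sampling, and the accompanying
    burden-versus-age and hits-versus-stem-cell-division correlation
    analyses.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
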