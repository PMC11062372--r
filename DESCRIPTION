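Package: fmtgraft
Title: Donor-Specific ASV Engraftment and Responder Prediction for FMT Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for fecal microbiota transplantation (FMT)
    cohorts with paired donor and recipient 16S amplicon sequence variant
    (ASV) tables. Partitions each recipient's post-FMT community into
    donor-specific, shared, recipient-specific and novel ASVs, tracks
    donor-specific ASV retention and per-ASV engraftment rates over time,
    computes rarefied Chao1 richness dynamics and Bray-Curtis principal
    coordinates with environmental vector fitting (permutation inference),
    stratifies recipients into insulin-resistance responders by the sign of
    their HOMA2-IR change, and screens baseline predictors of response with
    a replicated leave-one-out random-forest protocol (AUC-ROC, out-of-bag
    error, averaged variable importance). Includes a synthetic donor and
    recipient cohort generator with known ground truth for validating every
    stage, univariate association statistics with donor-adjusted ANCOVA and
    Benjamini-Hochberg FDR, and a deterministic end-to-end pipeline driver.
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
    pROC,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
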