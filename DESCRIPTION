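Package: wsirisk
Title: Whole-Slide Image Features and Stacked Risk Scores for Recurrence-Free Survival
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, simulation-backed pipeline for image-based
    recurrence-free-survival (RFS) risk stratification in hepatocellular
    carcinoma. Generates H&E-like synthetic slides with known nuclear
    morphology and simulated cohorts with known survival structure; extracts
    18 global gray-level features and 135 aggregated nucleus-shape features
    (including the min-max rate heterogeneity statistic) per slide; fits
    domain-wise Lasso-Cox risk scores with stacked score integration over
    repeated random train/test splits; evaluates models with Harrell's
    C-index and IPCW time-dependent AUC; assesses significance with a
    permutation null; and stratifies patients by median risk score with
    Kaplan-Meier curves, log-rank tests and per-unit hazard ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    glmnet,
    survival,
    MASS,
    stats,
    utils,
    graphics,
    grDevices,
    png,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
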