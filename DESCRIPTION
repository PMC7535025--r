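Package: anemetrics
Title: Inflammation-Adjusted Iron Biomarkers and Anemia Determinants in
    Lactating Women
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-sectional micronutrient surveys of women of
    reproductive age: a seeded Gaussian-copula synthetic cohort generator
    calibrated to published biomarker medians, threshold prevalences and
    pairwise correlations; regression-based (BRINDA-style) inflammation
    adjustment of ferritin and soluble transferrin receptor; altitude
    correction of hemoglobin; the Cook body-iron index; anemia, iron-status,
    inflammation-stage and zinc-status classification with prevalence
    summaries; HFIAS food-insecurity scoring with the FANTA category rules;
    an asset-based PCA wealth index with quintiles; and the two-stage
    determinant models (multiple linear regression for hemoglobin with
    squared semipartial correlations and VIF screening, and a bivariate
    screen followed by multivariate logistic regression for anemia with
    odds ratios).
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
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
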