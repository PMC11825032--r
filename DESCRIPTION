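Package: smoltsort
Title: Mixture-Model Thresholds for Life-History Classification of Hatchery Steelhead
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies juvenile hatchery steelhead (Oncorhynchus mykiss) into
    life-history categories from morphology and reproductive physiology.  Fits
    univariate Gaussian finite mixture models (one to three components) by EM
    with BIC model selection, derives decision thresholds at the intersections
    of adjacent weighted component densities, gates males into immature,
    maturing or mature status from a multi-marker panel (pituitary fshb and
    lhb, testis amh and igf3, gonadosomatic index, plasma 11-ketotestosterone),
    predicts migrant versus residual status from fork length and maturation,
    and compares groups with Pearson chi-square tests for equality of
    proportions.  Includes a seeded synthetic cohort generator with known
    component structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
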