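Package: dorsalvessel
Title: Scoring and Inference for Cardiac Cell-Division Defects in the
    Drosophila Dorsal Vessel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying cell-division defects in the Drosophila
    embryonic dorsal vessel (the linear heart tube). Hemisegment-level Svp and
    Tin cardial-cell counts are scored against the wild-type anatomical
    blueprint (104 cardial cells; 2 Svp + 4 Tin per hemisegment, 2 Svp + 2 Tin
    in A8), aggregated to embryo-level defect proportions, and compared between
    genotypes with a permutation (randomization) test on an indicator-variable
    linear model, the appropriate cluster-respecting inference for correlated
    hemisegments. Also included: Welch unequal-variance t-tests, one-way ANOVA,
    BCa bootstrap confidence intervals, lumen-width region comparisons, and a
    seeded beta-binomial synthetic-cohort generator for validating the whole
    pipeline without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    boot,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
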