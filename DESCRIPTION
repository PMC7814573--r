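Package: felir
Title: Insulin Resistance Surrogates, Biological Variation and Body
    Composition in Cats
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of feline insulin-resistance surrogates: HOMA-IR
    computation and cohort screening, biological-variation indices
    (unbounded-REML nested variance components on the natural-log scale,
    Cole coefficients of variation with Wald confidence intervals, index
    of individuality, asymmetric reference change values), robust
    Box-Cox reference intervals with bootstrap confidence limits,
    body-fat percentage from computed-tomography Hounsfield-unit
    histograms, and cohort statistics (Wilcoxon rank-sum comparisons,
    Noether power for the rank-sum test, ln-linear regression of
    analytes on body fat), together with seeded synthetic-data
    generators emulating a feline obesity study so every stage is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    withr
Suggests:
    lme4,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
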