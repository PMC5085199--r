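Package: rommeta
Title: Ratio-of-Means Meta-Analysis of a Diagnostic Biomarker
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative synthesis toolkit for study-level comparisons of a
    positive continuous biomarker (such as serum thyroid-stimulating hormone)
    between cases and controls. Implements the ratio-of-means effect measure
    with a delta-method variance, fixed-effect and DerSimonian-Laird
    random-effects pooling with Q, I-squared and tau-squared heterogeneity
    statistics, subgroup analysis with between-group contrasts, leave-one-out
    sensitivity analysis, REML random-effects meta-regression, Egger and Begg
    small-study-effect tests, funnel and Galbraith plot coordinates,
    category-count odds-ratio pooling, median/range to mean/SD conversion,
    and a cut-off-stratified diagnostic-accuracy arm (logit-scale pooled
    sensitivity and specificity, likelihood ratios, Moses-Littenberg summary
    ROC and its area). Includes a synthetic study-level data generator with
    known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
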