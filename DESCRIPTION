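Package: utfmp
Title: Urinary Total Fluorescent Metabolome Profile Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for synchronous fluorescence spectroscopy of
    urine as a non-invasive cancer screening modality. Reads wide-format
    spectral cohorts on a fixed 250-550 nm excitation grid, smooths them with
    a Savitzky-Golay filter, constructs urinary total fluorescent metabolome
    profiles (uTFMP), segments them into nine fluorophore zones, and derives
    zone summaries, ternary peak codes and the Z4a/Z5 and Z6/Z7 spectral-marker
    ratios. Provides group-difference testing (Shapiro-Wilk gated
    Kruskal-Wallis with Dunn/Bonferroni post hoc, or ANOVA with Tukey), ROC
    analysis with Wilson score confidence intervals, PLS-DA with R2/Q2, and a
    repeated stratified cross-validation suite of four classifiers (random
    forest, RBF support vector machine, ridge logistic regression, stochastic
    gradient descent). A seedable synthetic cohort generator emulates a
    three-group gynecological cohort so that every stage is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    ranger,
    e1071,
    glmnet,
    mixOmics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
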