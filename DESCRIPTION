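Package: mcabif
Title: Morphometric and Hemodynamic Case-Control Analysis of Middle
    Cerebral Artery Bifurcations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derived morphometric indices, principle-of-minimum-work
    optimality metrics and Doppler hemodynamic indices for middle cerebral
    artery (MCA) bifurcations, together with the case-control inference
    stage used to screen them as aneurysm predictors: nonparametric group
    comparisons, a univariate-to-multivariate logistic regression pipeline
    with a correlation-based variable screen, and ROC analysis with Youden
    cut-offs. Includes a seeded synthetic-cohort generator calibrated to
    published group summary statistics (aneurysmal, contralateral and
    bilateral control bifurcations) so the full pipeline can be exercised
    end-to-end without patient data, plus a weighted-Fermat-point numerical
    oracle for the closed-form optimal branching angles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
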