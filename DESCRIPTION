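Package: kidfitr
Title: Diagnostic Accuracy Analysis for the KidFit Pediatric Fitness Screen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating the KidFit screening tool, a two-part field
    screen (Speed and Agility Motor Screen time plus Modified Shuttle
    Test-Paeds score) for identifying children with overweight or obesity,
    reduced motor proficiency or reduced cardiorespiratory fitness. Provides
    a seedable synthetic-cohort generator with latent-factor correlation
    structure, the screening decision rule and reference-standard
    classifications (CRF bands, BMI categories from LMS growth references,
    motor quartiles), complete two-by-two diagnostic-accuracy statistics
    (sensitivity, specificity, predictive values with Wald standard errors,
    likelihood-ratio and odds-ratio confidence intervals with
    Haldane-Anscombe correction, efficiency rates, exact tests, ROC/AUC with
    Hanley-McNeil standard errors and accuracy banding), concurrent-validity
    models (multiple regression with standardized betas, pooled t-tests) and
    an end-to-end simulate-classify-evaluate-report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
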