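Package: raschval
Title: Rasch Validation of Dichotomous Symptom Scales
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Conditional maximum likelihood estimation of the dichotomous
    Rasch model and a complete scale-validation workflow for binary symptom
    inventories: dimensionality assessment by parallel analysis, item fit by
    information-weighted (infit) mean squares, local independence by Yen's Q3
    residual correlations with Holm adjustment, differential item functioning
    by Mantel-Haenszel and Breslow-Day tests with a tau-squared summary of
    differential test functioning, and reliability by Cronbach's alpha and the
    Person Separation Index. Includes an iterative item-elimination pipeline
    with calibration/validation sample splitting, Wright-map output, and a
    synthetic response generator with plantable model violations (misfit,
    DIF, local dependence, multidimensionality) for method checking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
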