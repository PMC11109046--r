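Package: cvmstage
Title: Cervical Vertebral Maturation Staging from Cephalometric Landmarks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative staging of cervical vertebral maturation (CVM) in
    female adolescents from 15 cephalometric landmarks on the second to
    fourth cervical vertebrae. Computes the 24 morphometric parameters
    (concavity depths, body heights and widths, their ratios,
    antero-superior angles and inter-vertebral distances), applies a
    published cascade staging algorithm (a proportional-odds cumulative
    logit model over four condensed maturation stages followed by a binary
    logistic disambiguator for the two most mature stages), and reproduces
    the model-development pipeline: Spearman feature screening,
    maximum-likelihood proportional-odds fitting with Wald inference,
    Brant proportional-odds diagnostics and variance-inflation-factor
    multicollinearity checks. Includes seeded synthetic cohort generators
    calibrated to the published per-stage demographics and pooled feature
    statistics, and confusion-matrix evaluation with per-stage precision,
    recall and F1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
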