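Package: glioscreen
Title: Phenotypic-Screen Triage and Machine-Learning Virtual Screening for
    Glioblastoma Stem-Cell Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processes high-content phenotypic screening data from panels of
    heterogeneous glioblastoma stem-cell lines into machine-learning training
    sets and virtual-screening hit lists. Provides plate-wise normalisation of
    nuclei counts to DMSO controls, a concentration- and cell-line-sensitive
    binary activity labelling rule, physicochemical featurisation with
    continuous-Tanimoto diversity diagnostics, Monte-Carlo ensembles of
    gradient-boosted tree classifiers gated on a naive accuracy baseline,
    ensemble scoring of external compound libraries with hit selection and
    training-analogue flagging, and four-parameter logistic dose-response
    fitting with bootstrap confidence intervals. A synthetic-screen generator
    with known ground truth makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    data.table,
    jsonlite,
    minpack.lm,
    pROC,
    ranger,
    stats,
    utils,
    xgboost,
    yaml,
    ChemmineR,
    ChemmineOB
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
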