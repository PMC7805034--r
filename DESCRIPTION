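Package: sabresponse
Title: Predicting Pathologic Complete Response to Lung SABR from Dynamic
    FDG-PET and CT Perfusion Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-imaging analysis pipeline for predicting pathologic
    complete response (pCR) of early-stage non-small cell lung cancer to
    stereotactic ablative radiation therapy (SABR). Implements forward
    simulation and nonlinear fitting of a flow-modified two-tissue compartment
    model for dynamic [18F]FDG-PET time-activity curves, model-based fitting
    of the Johnson-Wilson (adiabatic approximation) impulse-residue model for
    CT-perfusion enhancement curves, SUV and percent-change biomarkers,
    single-lesion RECIST 1.1 and PERCIST 1.0 response classification,
    CART-style recursive partitioning with a minimum-node-size rule, tie-aware
    ROC concordance with DeLong variance and the paired DeLong test, plus a
    seeded synthetic-cohort generator and an end-to-end evaluation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    pROC,
    rpart
Config/testthat/edition: 3
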