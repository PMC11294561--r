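Package: relead
Title: Reduced-Lead 12-Lead ECG Reconstruction, Simulation and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Synthesizes the six precordial leads of a 12-lead
    electrocardiogram from a reduced input lead set (leads I+II or
    I+II+V3) with residual one-dimensional convolutional networks, and
    derives the remaining limb leads exactly from the Einthoven-Goldberger
    identities.  Includes a dipole-source synthetic ECG generator (rank-3
    heart-vector projection with normal and ST-elevation morphologies), an
    acute myocardial-infarction detection classifier used as an automatic
    judge of reconstruction fidelity, evaluation statistics (MSE, R2 with
    confidence intervals, ROC/AUC, clinical reader metrics, a one-sided
    non-inferiority z-test for two proportions), exact Shapley lead
    attribution, and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
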