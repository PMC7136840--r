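Package: clout
Title: Mortality Prediction from Longitudinal EHR Encounters with
    Multi-View Latent Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the CLOUT family of mortality-prediction models for
    longitudinal electronic-health-record encounter sequences: per-encounter
    diagnosis, medication and abnormal-laboratory indicator views are fused
    through a three-view correlational autoencoder into a shared latent space
    and classified by an attention-pooled LSTM. Includes cohort construction
    rules (two-or-more-encounter filter, last-encounter removal, reproducible
    70/10/20 splits), a synthetic-cohort generator with planted risk markers,
    zero-out ablation attribution with patient- and population-level risk
    factor ranking and stratified review sampling, classification metrics,
    rater-agreement analysis, and an end-to-end experiment pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Matrix,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
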