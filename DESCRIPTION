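Package: fmtforge
Title: Donor-Based Prediction and Design of Fecal Microbiota Transplant Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts post-transplant recipient microbiome properties (Shannon
    diversity, taxon abundance and presence) and clinical success from the donor
    microbiome alone, using a taxonomy-structured image embedding consumed by a
    small convolutional network, alongside a bank of classical baselines.
    Quantifies donor versus recipient-background effects through a hierarchy of
    between-recipient distances (SDSR/SDDR/DDDR), ranks candidate donors by
    predicted outcome, and designs sparse synthetic transplant communities with
    a generative genetic algorithm driven by the trained predictor under a
    sparsity penalty. Includes a synthetic paired donor-recipient cohort
    generator with a known transfer model for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Matrix,
    glmnet,
    e1071,
    ranger,
    xgboost,
    nnet,
    caret,
    pROC,
    data.table
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
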