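Package: molfinetune
Title: Transfer Learning for SMILES-Based Molecular Property Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Self-supervised pretraining of a character-level SMILES language
    model (an AWD-LSTM next-token predictor) and its supervised fine-tuning
    into QSPR/QSAR regression and classification models, following the
    ULMFiT-style regimen: one-cycle learning-rate scheduling, discriminative
    layer-wise learning rates, and gradual unfreezing over four layer groups.
    Includes character-level SMILES tokenization, SMILES-enumeration data
    augmentation for training (with Gaussian label noise for regression and
    class rebalancing for classification) and test-time augmentation,
    Bemis-Murcko scaffold splits, RMSE/AUROC benchmarking over repeated
    splits, corpus curation, and a seeded generator of synthetic SMILES
    corpora and labelled datasets so the full pipeline runs end-to-end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
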