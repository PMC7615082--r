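Package: hierehr
Title: Hierarchical Transformers and Self-Supervised Pre-Training for Long
    Longitudinal Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Risk prediction from long multimodal longitudinal electronic
    health records (EHR). Provides cohort construction (baseline-date
    selection, incident labelling, continuous-measure binning, sequence
    encoding), a two-level hierarchical transformer encoder that extends the
    receptive field over thousands of records via a sliding-window local
    feature extractor and a global feature aggregator, a flat truncating
    transformer baseline, an adapted BYOL (bootstrap-your-own-latent)
    self-supervised pre-training scheme with exponential-moving-average
    target network and two-level augmentation, evaluation protocols
    (AUROC/AUPRC, length-subgroup analysis with positive-rate-matched
    bootstrap, training-fraction curves, modality ablation), and a seeded
    synthetic EHR cohort generator with a plantable long-range risk signal.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
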