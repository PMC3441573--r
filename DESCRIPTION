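Package: crmx
Title: Cis-Regulatory Module Detection and Expression Prediction from
    Co-Localized Transcription Factor Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects cis-regulatory modules (CRMs) from co-localized
    transcription factor (TF) ChIP-Seq peaks, maps them to gene promoters,
    and models each target gene's log expression across cell types as an
    additive spline function of the expressions of the TFs bound in its
    promoter CRM.  Prediction accuracy is assessed by cross-validation and
    calibrated against resampled-TF null models via a bootstrap p-value.
    Includes cross-cell-line CRM comparison (reciprocal overlap, Hamming and
    Jaccard dissimilarity, dissimilarity-versus-prediction-error analysis,
    TF enrichment at differentially expressed genes, TF co-occurrence
    clustering) and a synthetic-data generator with known ground truth so
    the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    limma,
    ape,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
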