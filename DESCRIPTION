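Package: trfe
Title: Transfer Recursive Feature Elimination for Cross-Subject EEG Emotion Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Feature selection and classification tools for cross-subject
    EEG-based emotion recognition in the valence-arousal framework. Implements
    a linear least-squares support vector machine trained by a direct solve of
    the dual KKT system, classical margin-based recursive feature elimination
    (RFE), and transfer RFE (T-RFE), which ranks features by a weighted
    combination of classification-margin loss and the source-target domain
    distance remaining after each feature's removal. Includes a 440-dimensional
    EEG spectral/asymmetry/time-domain feature extractor for the standard
    32-channel montage, adaptive rating-threshold labeling by 2-means
    clustering of self-assessment ratings, synthetic multi-subject data
    generators with planted transferable structure, and a leave-one-subject-out
    evaluation harness comparing subject-specific and subject-generic schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
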