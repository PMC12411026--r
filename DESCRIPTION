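Package: attenuskin
Title: Dual-Modal OCT Attenuation and Raman Spectral Analysis of Skin Lesions
Version: 0.1.0
Authors@R: person("attenuskin", "developers", email = "dev@attenuskin.invalid",
    role = c("aut", "cre"))
Description: Tools to discriminate malignant melanoma from benign nevi with a
    dual-modal optical workflow. Fits the two-way Lambert-Beer exponential
    decay to each OCT A-scan to estimate effective attenuation coefficients
    with fit-quality metrics, aggregates them into binned feature vectors,
    and classifies lesions with a cross-validated linear support vector
    machine including interpolated mean ROC curves and per-sample majority
    reports. Preprocesses Raman spectra (cosmic-ray removal, Savitzky-Golay
    smoothing, fingerprint-region normalization, arPLS baseline correction)
    and computes group mean, confidence-interval and difference spectra. A
    seeded synthetic-data module emulates both modalities so that every
    stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
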