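Package: oxinet
Title: Neural-Network Estimation of Sleep-Apnea Indices from Pulse Oximetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the apnea-hypopnea index (AHI) and the oxygen
    desaturation index (ODI) from a single-channel blood oxygen saturation
    (SpO2) signal. Full-night recordings are split into overlapping
    ten-minute epochs, downsampled to 0.5 Hz, and regressed to per-epoch
    indices by a small feedforward network trained with scaled conjugate
    gradient backpropagation and validation-based early stopping; epoch
    predictions are averaged into full-night indices and classified into
    obstructive sleep apnea (OSA) severity categories. Includes an
    annotated synthetic oximetry-cohort simulator with known ground-truth
    indices, an AASM-2007-style desaturation detector, and an evaluation
    battery (error statistics, severity confusion matrices, intraclass
    correlation with confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
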