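Package: qaisdsnn
Title: Quantum-Immune Spiking Network Segmentation of Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Brain-tumor segmentation toolkit combining a variational
    quantum-matched-filter denoiser (QMFT), a spiking-flavoured random-hidden-layer
    segmentation network with a generalized-inverse output solve (DSNN),
    fully-connected conditional-random-field (CRF) refinement by mean-field
    inference, and a quantum artificial-immune-system optimizer (QAIS) for the
    decision layer. Ships a seeded multi-contrast brain phantom generator so the
    whole pipeline is testable without clinical data, plus Dice/PSNR/ROC
    evaluation and PNG/NIfTI input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    png,
    RNifti,
    stats,
    utils
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
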