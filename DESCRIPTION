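Package: sigdecon
Title: Drug Target Deconvolution from Perturbation Proteome Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deconvolutes targets and mechanism-related proteins of cytotoxic
    compounds from expression-proteomics signature libraries. Implements the
    TMT reporter-intensity normalization chain (per-channel median
    equalization, log2 fold change versus control mean, global median
    centering), from-scratch NIPALS PLS-DA and OPLS-DA with variable
    influence on projection (VIP) and seven-fold cross-validated Q2,
    one-versus-rest compound contrasts with specificity scoring, multi
    cell-line model merging, randomized panel-size minimization experiments,
    correlation-based compound and protein clustering, and a synthetic
    multiplexed-screen generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
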