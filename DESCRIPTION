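Package: synodce
Title: Quantitative DCE-MRI Analysis of Synovitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end quantitative analysis of dynamic contrast-enhanced MRI
    (DCE-MRI) of the synovium. Implements spoiled gradient-echo (SPGR)
    relaxometry with variable flip angle T1 mapping and signal-to-concentration
    conversion, a population-averaged arterial input function with haematocrit
    correction, voxelwise extended Tofts pharmacokinetic fitting (Ktrans, ve,
    vp, IAUC60), semiautomatic segmentation of enhancing pannus by
    shuffle-transform subtraction and Otsu thresholding, and the
    imaging-biomarker technical-validation statistics (variance components,
    ICC, wSD/wCV, smallest detectable difference, RMSCV, concordance
    correlation, standardised mean difference, responsiveness counts). A
    digital-phantom generator simulates full two-group longitudinal cohorts
    with known ground truth so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
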