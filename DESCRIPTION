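Package: capox
Title: Capillary Transit Time Based Modelling of Cerebral Oxygen Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Biophysical estimation of the cerebral oxygen extraction fraction
    (OEF) from perfusion-derived transit time statistics. Solves the
    single-capillary oxygen transport equation with Hill-equation hemoglobin
    binding, integrates extraction over a gamma distribution of capillary
    transit times parameterized by mean transit time (MTT) and capillary
    transit time heterogeneity (CTH), and calibrates the model's two free
    parameters (tissue oxygen tension and the oxygen transfer rate constant)
    against PET oxygen extraction measurements. Includes a minimal
    single-tissue-compartment PET kinetic arm (OEF = K1/CBF, CMRO2, water
    extraction correction), a seeded synthetic cohort generator, voxelwise
    map evaluation, and Pearson/Bland-Altman agreement reporting between
    model and PET OEF.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    pracma,
    MASS,
    minpack.lm,
    stats,
    graphics,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti
Config/testthat/edition: 3
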