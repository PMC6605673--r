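Package: dxacv
Title: Cross-Validation of Body Composition Prediction Equations Against DXA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-validates anthropometry and bioelectrical-impedance (BIA)
    prediction equations for body fat and fat-free mass against dual-energy
    X-ray absorptiometry (DXA) as the reference method. Provides a
    machine-readable registry of published skinfold and BIA equations with
    per-equation age-range eligibility and unit handling, the Siri body-density
    conversion, the full agreement-statistics chain (Pearson screen, one-sample
    t-test, Bland-Altman limits of agreement, proportional-bias regression and
    a staged validity verdict), measurement-quality utilities (triplicate
    skinfold acceptance, technical error of measurement, repeatability CV,
    ISCD least significant change), and a synthetic-cohort generator with
    controllable equation-reference bias structure for testing the whole
    pipeline without participant-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
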