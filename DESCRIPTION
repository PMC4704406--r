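Package: ftmirplasma
Title: FT-MIR Plasma Calibration for the Dairy-Cow Metabolic Profile
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric calibration of Fourier-transform mid-infrared (FT-MIR)
    transmittance spectra of bovine blood plasma against reference clinical
    chemistry. Implements spectral window selection with water-band exclusion,
    reference-band normalisation, absorbance conversion and autoscaling; NIPALS
    PLS1 regression with grouped cross-validation and PRESS-based factor
    selection backed by a randomization model-comparison test; and the
    chemometric quality-metric suite (RMSECV, R2, RER, RPD with interpretation
    bands, duplicate-based repeatability). Ships a Beer-Lambert forward
    simulator that generates analyte panels and paired duplicate plasma spectra
    with known ground truth, so the whole pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
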