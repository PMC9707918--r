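Package: angioffr
Title: Personalized Microvascular Resistance for Angiography-Derived Fractional Flow Reserve
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Reduced-order modelling of coronary pressure and flow for computing
    virtual fractional flow reserve (vFFR) from vessel geometry, with the distal
    boundary expressed as a coronary microvascular resistance (CMVR). Provides the
    inverse computation of vessel-specific CMVR from measured aortic and distal
    pressures, sparse polynomial (FROLS) identification of CMVR from clinical,
    angiographic and echocardiographic predictors with a repeated-split
    term-frequency protocol, myocardial jeopardy indices from scored coronary trees,
    a synthetic cohort generator for end-to-end testing, and the agreement and
    diagnostic-accuracy statistics (Bland-Altman, ROC AUC, 2x2 tables) used to
    compare vFFR against invasively measured FFR.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
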