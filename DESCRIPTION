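Package: normacurve
Title: Simultaneous Quantification and Normalization of Reverse-Phase
    Protein Array Dilution Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates relative protein expression from reverse-phase
    protein array (RPPA) serial-dilution series by fitting a shared
    non-parametric response curve across all samples on an array
    (SuperCurve), and extends the fit to a penalized additive model that
    simultaneously normalizes for background fluorescence (a negative
    control array), total spotted protein (a total-protein-stain array)
    and linear spatial bias, with smoothing parameters selected by REML.
    Includes the validation machinery for such models (cross-validation,
    amount-effect and spatial-effect tests, variance components, power
    and dilution-design analyses) and a synthetic spike-in simulator
    emulating a two-block randomized array design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    mgcv,
    lme4,
    car,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
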