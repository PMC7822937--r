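Package: ribchron
Title: Multifactorial Age-at-Death Estimation from Rib Cortical Bone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating age at death from physicochemical and
    mechanical properties of rib cortical bone. Extracts nanoindentation
    mechanics (Oliver-Pharr hardness, modulus, creep and elastic work
    ratio), Vickers microhardness, thermogravimetric and calorimetric
    fractions and enthalpies, ATR-FTIR matrix indices, X-ray diffraction
    crystallite metrics (Scherrer coherence lengths, Williamson-Hall
    size/strain separation, lattice parameters) and optical porosity from
    raw modality data; screens parameters against age; builds stepwise-AIC
    regression models with collinearity, heteroscedasticity and residual
    diagnostics and leave-one-out cross-validation; and applies published
    fixed estimation equations. A forward simulator generates per-specimen
    parameter tables with a configurable age-correlation structure and
    renders raw curves, spectra, diffraction patterns and porosity masks so
    every extraction stage can be validated by round-trip recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lmtest,
    minpack.lm,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
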