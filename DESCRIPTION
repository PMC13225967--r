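Package: thzash
Title: Terahertz Time-Domain Spectroscopy Chemometrics for Flour Ash Content
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested pipeline for quantifying wheat-flour ash content from
    terahertz time-domain spectroscopy (THz-TDS): optical-parameter extraction
    from time-domain pulses (absorption coefficient, transmittance, refractive
    index), signal-to-noise valid-band screening, spectral preprocessing
    (Savitzky-Golay smoothing and derivatives, SNV, MSC), stratified
    Kennard-Stone calibration/prediction partitioning, characteristic-frequency
    selection (SPA, CARS, GA, BOSS), regression modelling (PLSR, MLR, PCR, SVR)
    and chemometric evaluation (Rc, RMSECV, Rp, RMSEP, RPD, Bias with RPD
    grading). Includes a seeded synthetic-cohort generator whose forward model
    links frequency-dependent attenuation to a known ash value, so every stage
    of the pipeline is exercisable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
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
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
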