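Package: phenomap
Title: Hyperspectral Prediction and Mapping of Total Phenolic Content in Plants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometrics pipeline for non-destructive estimation of total
    phenolic content (mg/g dry weight) in rosette plants from hyperspectral
    reflectance imagery. Covers ENVI hypercube input/output, white/dark
    reflectance calibration, band-composite canopy segmentation, random-region
    mean-spectrum extraction, spectral pretreatments (normalisation, MSC, SNV,
    Savitzky-Golay derivatives), NIPALS partial least squares regression with
    cross-validated latent-variable selection, discrete-cosine-transform
    waveband reduction, and per-pixel chemical concentration mapping. Includes
    a synthetic scene generator that emulates VIS/NIR and SWIR acquisitions of
    plants with known phenolic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    signal,
    EBImage,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    rpart,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
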