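Package: nirmc
Title: Moisture Content of Intact Green Coffee Beans from NIR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Chemometric workflow for predicting the moisture content (wet
    basis) of intact green coffee beans from near-infrared diffuse
    reflectance log(1/R) spectra. Provides tidy spectra containers and I/O,
    the gravimetric (ISO 6673 style) reference computation, a catalogue of
    spectral pre-treatments (smoothing, Savitzky-Golay derivatives,
    normalisation, baseline correction, SNV, MSC/EMSC, OSC), PCA with
    Hotelling's T-squared outlier screening, NIPALS partial least squares and
    multiple linear regression calibration with leave-one-out cross
    validation and leverage-corrected errors, regression-coefficient
    wavelength selection, validation statistics (RMSEP, SEP, bias, RPD), and
    a synthetic-spectra generator that emulates the study design for testing
    the full pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
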