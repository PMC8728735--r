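Package: amorphkit
Title: Dielectric Relaxation and Dissolution Analysis for Amorphous Drugs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for the solid-state characterization of
    amorphous pharmaceuticals by broadband dielectric spectroscopy and
    intrinsic dissolution testing. Fits per-temperature dielectric loss
    spectra with the Havriliak-Negami function plus a dc-conductivity term,
    characterizes alpha-peak shape through the one-sided Fourier transform
    of the Kohlrausch-Williams-Watts stretched exponential, converts
    Havriliak-Negami times to structural relaxation times, fits the
    Vogel-Fulcher-Tammann law and extracts the glass-transition temperature
    at a 100 s relaxation time, predicts glassy-state relaxation times by
    time-temperature superposition (master-curve shifting of flank-only
    sub-Tg spectra), and estimates intrinsic dissolution rates with
    replicate statistics, fold-changes, and kinetic regime-change
    detection. Includes seeded synthetic-data generators for every stage.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
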