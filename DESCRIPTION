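Package: milkFTIR
Title: Chemometric Analysis of Dry-Film FTIR Milk Spectra Across Lactation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for exploring dry-film Fourier-transform infrared (FTIR)
    spectra of bovine milk collected through early lactation. Provides an S4
    container for spectral sets with per-sample metadata, spectral
    preprocessing (Savitzky-Golay second derivative, extended multiplicative
    signal correction with polynomial baseline terms, wavenumber-region
    selection), partial least-squares regression calibration of fatty-acid
    features, sparsity-optimised PLS discriminant classification of lactation
    stage under leave-one-cow-out cross-validation, principal component
    exploration of days-in-milk and parity structure, a blood
    beta-hydroxybutyrate based subclinical-ketosis comparison, and a seeded
    synthetic-cohort generator that emulates the statistical structure such
    studies assume so the whole workflow is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), methods
Imports:
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    signal
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
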