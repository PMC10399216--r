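Package: canecrush
Title: High-Throughput NIRS Phenotyping of Sugarcane Stalk Crushing Strength
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for high-throughput phenotyping of stalk mechanical
    strength in sugarcane germplasm. Implements laboratory force-curve
    analysis (first-peak crushing strength with replicate quality metrics),
    near-infrared spectral pretreatment (offset/baseline removal, SNV, MSC,
    min-max normalisation, Savitzky-Golay derivatives), NIPALS partial least
    squares calibration with cross-validated rank selection and a
    pretreatment-by-wavelength-region optimisation search, GH (global
    Mahalanobis) outlier exclusion in principal-component score space,
    R-squared/RMSE/RPD model evaluation, and model-based multi-year
    germplasm screening. A synthetic-data generator emulating the
    statistical structure of online NIRS germplasm panels makes the whole
    pipeline testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
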