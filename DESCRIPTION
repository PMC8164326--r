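Package: nirscane
Title: High-Throughput NIRS Calibration of Sugarcane Cell-Wall Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Chemometric calibration workflow for predicting sugarcane
    bagasse cell-wall traits (cellulose crystallinity index, acid-soluble,
    acid-insoluble and total lignin content and proportion) from
    near-infrared spectra. Implements the ten scatter-correction
    pretreatments used in commercial NIRS software (offset elimination,
    detrending, standard normal variate, min-max normalization,
    multiplicative scatter correction, Savitzky-Golay derivatives and
    first-derivative combinations), wavelength-interval selection, global-H
    (Mahalanobis) outlier screening, NIPALS partial least squares with
    cross-validated rank selection, external validation, exhaustive
    pretreatment-by-region model search with RPD-based ranking, and
    F-test / Fisher-z model comparison statistics. Also provides the Segal
    crystallinity index computation from X-ray diffractograms, the
    two-step acid-hydrolysis lignin arithmetic, and a synthetic-data
    generator with known latent structure so the entire pipeline is
    testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
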