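Package: bmcpod
Title: Benchmark-Concentration Modelling and Point-of-Departure Derivation
    for High-Throughput In Vitro Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for deriving points of departure (PODs) from
    direct-infusion mass spectrometry (DIMS) metabolomics feature tables of
    chemically exposed cell cultures. Provides a synthetic-data generator
    with planted concentration-response ground truth, the full quality
    control and preprocessing cascade (internal-standard mass-drift
    correction, outlier removal, blank and presence filters, QC-anchored
    signal drift correction, probabilistic quotient normalisation, RSD
    filtering, k-nearest-neighbour imputation, generalised log transform,
    PCA outlier removal), continuous benchmark-concentration (BMC) modelling
    with seven dose-response models, profile-likelihood BMCL/BMCU bounds and
    dual benchmark-response retention criteria, rank-ordered POD derivation
    by three methods, and putative metabolite annotation by adduct m/z
    matching within a ppm tolerance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
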