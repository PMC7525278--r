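Package: aquarisk
Title: Water Quality Indices, Irrigation Suitability, Hydrochemical Facies
    and Noncarcinogenic Health Risk for River Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing river and groundwater monitoring tables of
    physicochemical parameters and heavy metals. Screens concentrations
    against WHO drinking-water guidelines, computes the weighted-arithmetic
    Water Quality Index, irrigation suitability indices (SAR, Na%, RSC, MAR,
    Kelly ratio) with salinity/alkalinity hazard classes, Gibbs and Chadha
    hydrochemical facies, deterministic USEPA noncarcinogenic health risk
    (average daily dose, hazard quotient and hazard index for adult and child
    receptors via ingestion and dermal contact), and source-apportionment
    statistics (Pearson correlation with significance flags, KMO, Bartlett's
    sphericity, correlation-matrix PCA with varimax rotation). Includes a
    seeded synthetic-data generator that reproduces published marginal
    summaries via moment-matched truncated normals with optional rank-based
    correlation imposition, so every pipeline stage is testable without
    access to raw field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
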