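Package: copollution
Title: Assessment of PM2.5-Ozone Compound Pollution, Exposure Risk, and
    Synergistic Change in Urban Monitoring Networks
Version: 0.1.0
Authors@R:
    person("copollution", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools to assess compound fine-particulate (PM2.5) and surface
    ozone (O3) pollution from daily city-level monitoring series: quality
    control with valid-day quotas and MDA8 ozone aggregation, a four-class
    compound-pollution typology, Mann-Kendall trend tests with tie-corrected
    variance, a six-type population exposure-risk classification, bivariate
    local and global Moran's I with conditional permutation inference,
    geographically weighted local correlation between co-pollutants and their
    precursors, and a four-quadrant classification of synergistic
    concentration change. Includes a synthetic multi-city data generator with
    a planted-truth ledger so the full pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
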