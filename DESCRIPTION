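Package: lakebloom
Title: Detection, Phenology and Trend Attribution of Lake Algal Blooms from
    Daily Multi-Band Reflectance
Version: 0.1.0
Authors@R: person("Lake", "Bloom Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify surface algal blooms in large lakes from daily
    multi-band Rayleigh-corrected reflectance composites. Pixels are classified
    with a normalized floating algae index (nFAI) threshold, a CIE chromaticity
    green-pixel screen, and a historical water-presence exclusion; daily bloom
    areas are converted to a cloud-weighted bloom frequency, smoothed with a
    15-day running mean, and summarized as annual onset, persistence and bloom
    frequency with ice-season and hemisphere handling. Per-lake linear trends
    are classified by sign and significance, global median series are expressed
    as relative growth rates, and bloom frequency is attributed to
    meteorological and nutrient drivers by correlation. A synthetic-scene
    simulator with known ground truth makes every stage testable without
    external satellite data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
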