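Package: resourcegaps
Title: Spatial Accessibility of Autism Diagnostic Resources
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates population placement from census-style region tables,
    assigns individuals to diagnostic centers by nearest-distance or
    tiered-radius random rules, and computes demand-to-supply metrics for
    autism diagnostic services: per-center resource load, location-indexed
    resource availability, resource-gap classification, distance-to-care
    summaries, and availability heatmap grids. Includes a seeded synthetic
    scenario generator (heavy-tailed region populations, population-weighted
    center placement, optional diagnosis-distance bias) so every stage of the
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
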