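Package: ecoclimex
Title: Mechanistic Ecoclimatic-Index Species Distribution Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A CLIMEX-style mechanistic climate-suitability engine built
    around the Ecoclimatic Index (EI): weekly trapezoidal growth indices for
    temperature and soil moisture, a weekly soil-moisture bucket model,
    linear cold/heat/dry stress accumulation, a degree-day persistence gate,
    and a three-class suitability map. Ships the adjusted parameter set for
    the invasive C4 grass Urochloa panicoides, a one-at-a-time sensitivity
    protocol over all fifteen species parameters, climate-change scenario
    transforms, greedy radius-based occurrence thinning and overlay
    validation, plus a seeded synthetic climate-grid generator so the whole
    pipeline runs without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
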