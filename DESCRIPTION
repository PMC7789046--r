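Package: agroclim
Title: Phenology-Linked Agro-Climate Indicators, Variety Optimization and
    Disease Risk for Winter Wheat
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dynamic winter-wheat phenology simulation (two-phase and
    six-sub-phase thermal-time models with vernalization and photoperiod
    correction), sixteen phenology-linked agro-climate risk indicators
    (non-parametric SPEI hydrological balance, excessive wetness, cold and
    heat stress day counts), exhaustive and genetic-algorithm search for
    variety thermal requirements minimizing climate impact, and a rank-based
    kernel copula model linking indicators to observed disease severity.
    Includes a seeded stochastic weather generator so every component can be
    exercised end-to-end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
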