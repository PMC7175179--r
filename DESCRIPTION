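Package: adcarbon
Title: Carbon Mass-Balance Analysis for Two-Stage Anaerobic Digestion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for carbon mass-balance analysis of two-stage (acidogenic +
    methanogenic) anaerobic digestion experiments. Computes per-period degrees
    of hydrolysis, acidogenesis, acetogenesis, protein hydrolysis and
    methanogenesis from reactor time series of liquid chemistry and normalized
    gas production; partitions weak acids into dissociated and undissociated
    (toxic) forms via Henderson-Hasselbalch and Ostwald dilution-law routes;
    analyses biochemical methane potential (BMP) bottle curves with blank
    correction and gas-mass-loss compensation; and projects bench-scale acetate
    yields to industrial scale. Includes a synthetic reactor, BMP and
    dilution-series generator with known ground truth so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
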