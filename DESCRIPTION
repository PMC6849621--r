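Package: ecodisorder
Title: Early-Warning Signals of Critical Transitions from Compositional
    Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects early-warning signals of critical transitions in
    community time series from the correlation of compositional disorder
    with biodiversity.  Compositional disorder is the nestedness
    temperature (0-100 degrees) of a sliding 15-sample species incidence
    matrix; biodiversity is Hill's N2 on square-root transformed
    percentage abundances.  The package provides a trait-structured
    Lotka-Volterra competition model of canary, keystone and weedy
    species, a stochastic agent-based community simulator under
    death-rate forcing, sequential pretransition/lead-in first-difference
    Pearson correlation diagnostics, sequential t-test (STARS) break-point
    detection with Huber-weighted regime means, an ARIMA forecasting
    interface, and seed-deterministic synthetic sediment-core generators
    for testing the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
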