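Package: ratiosense
Title: Ratio-Sensing Models of Carbon-Source Signal Integration in the
    Yeast GAL Pathway
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Steady-state models of how budding yeast integrates external
    galactose and glucose signals to decide whether to induce the GAL
    metabolic genes. Implements competitive binding of the two sugars to a
    communal transporter pool (with optional Hill cooperativity),
    competitive occupancy of the GAL1 cis-regulatory element by an
    activator and a repressor, the concatenation of both layers, and a
    library of network-motif variants (auto-regulation and feedforward
    loops) of the basic signal-integration unit. Simulates double-sugar
    titration response surfaces on log-spaced grids, extracts
    iso-induction decision fronts, fits their log-log slope and intercept,
    classifies the signal-integration pattern (ratiometric, threshold or
    compound), and verifies the analytic slope and intercept predictions
    of each circuit variant, including a census of all twenty-five
    activator/repressor regulatory configurations.
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
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
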