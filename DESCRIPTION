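Package: normsgame
Title: Multi-Population Norms Game on a Spatial Lattice
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stochastic simulator for the emergence of shared behavioral
    norms in heterogeneous populations with incompatible preferences.
    Agents on a fully occupied torus interact within a range R, earn
    coordination and preference payoffs, imitate more successful in-group
    neighbors proportionally to payoff differences, and err at a small
    flip rate. Optional costly peer punishment (behavior-based,
    preference-based, or adaptive group pressure) with sincere versus
    hypocritical sanction classification. Includes a mean-field
    (representative-agent) oracle, outcome classification, phase-diagram
    sweeps, scheduled parameter changes, snapshot and time-series I/O,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
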