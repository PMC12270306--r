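Package: spopulse
Title: Spo0A~P Pulsing Dynamics and Biofilm Matrix Deactivation in B. subtilis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic and stochastic models of the Bacillus subtilis
    sporulation phosphorelay and the SinI/SinR/SlrR biofilm matrix production
    network. Generates once-per-cell-cycle Spo0A~P pulses from a growth-rate
    dependent gene-dosage mechanism, simulates the bistable matrix switch
    under pulsatile, oscillatory and constant inputs, locates matrix
    deactivation thresholds (in Spo0A~P level and in cell-cycle length),
    runs Gillespie ensembles of the stochastic matrix network, and estimates
    effective two-state (telegraph) activation and deactivation rates from
    ensemble ON-fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
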