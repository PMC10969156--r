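Package: inforate
Title: Information-Geometry Measures for Ensembles of Stochastic Coupled
    Oscillators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates ensembles of a stochastic coupled Duffing-van der Pol
    oscillator model of EEG with the Euler-Maruyama scheme, estimates
    time-dependent probability densities with histogram binning (Rice's
    rule), and computes information-geometry measures on the resulting
    density sequences: information rate, information length, causal
    information rate and net causal information rate, together with the
    comparator measures differential entropy and transfer entropy. Includes
    stationary-window summaries, empirical measure distributions, power
    spectra with power-law fits, and an end-to-end pipeline contrasting
    eyes-open/eyes-closed parameter regimes for healthy-control and
    Alzheimer's-disease oscillator presets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
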