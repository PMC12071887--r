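Package: plateletkin
Title: Kinetic Modelling of Platelet Phenotype Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for kinetic analysis of platelet activation, aggregation,
    inhibition and exhaustion as measured by low-angle laser diffraction
    (light-scattering) aggregometry. Implements a six-state ordinary
    differential equation model of platelet phenotype transitions (resting,
    sphered, integrin-activated, aggregated, inhibited, exhausted) with
    Hill-type coupling of transition rate constants to agonist and inhibitor
    concentrations, forward simulation under scripted stimulation protocols
    (timed agonist/inhibitor additions, stir on/off), instrument-like trace
    synthesis, trace readouts (initial rates, areas under the curve,
    disaggregation), monoexponential rate-constant extraction, Hill
    dose-response fitting, desensitization-constant estimation, and
    global-plus-local estimation of experimentally inaccessible constants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
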