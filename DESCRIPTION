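Package: pkcross
Title: Noncompartmental and Bioequivalence Analysis of Crossover
    Pharmacokinetic Studies of Delayed-Release Stimulants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the pharmacokinetic analysis chain used in
    single-dose crossover studies of a delayed-release/extended-release
    oral formulation: noncompartmental analysis of concentration-time
    profiles (Cmax, Tmax, trapezoidal AUC, terminal rate constant,
    half-life, dose-normalised exposure, early-exposure fraction),
    average-bioequivalence statistics on log-transformed exposure metrics
    (geometric least-squares means, 90% confidence intervals, intrasubject
    CV, 0.8-1.25 equivalence verdicts) for 2x2 and 3x3 Latin-square
    designs, a one-compartment first-order absorption model with lag time
    (fitting to mean profiles, multiple-dose superposition, steady-state
    closed forms, accumulation ratios), and a seeded generator of
    synthetic crossover studies emulating evening-dosed delayed-release
    and morning-dosed immediate-release methylphenidate designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    minpack.lm,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
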