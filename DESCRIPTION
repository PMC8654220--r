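Package: oasim
Title: Open-Population Microsimulation of Osteoarthritis Burden and
    Intervention Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time microsimulation of osteoarthritis (OA) in an open
    adult population. Individuals age, enter and leave the population, update
    body mass index through an autoregressive log-BMI model, acquire OA from
    age-, sex- and BMI-dependent incidence, carry an eight-attribute Health
    Utilities Index Mark 3 (HUI3) health state updated by hierarchical
    proportional-odds models, use four classes of analgesics with pain
    benefits and side effects, and undergo primary and revision joint
    replacement surgery. Counterfactual intervention scenarios (targeted
    analgesic uptake, expanded surgical access, population BMI reduction) are
    compared against a base case under common random numbers, and burden
    reduction is reported as years lived with disability, years of life lost,
    disability-adjusted life years averted, quality-adjusted life years, and
    effectiveness ratios. Includes steady-state prevalence calibration, a
    synthetic structure-complete default parameter set, and one-way
    sensitivity analysis over registered parameters.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
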