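Package: pmslt
Title: Proportional Multistate Lifetable Modelling of Trans-Fat Elimination Policy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cost-effectiveness modelling of eliminating industrial trans-fatty
    acids from a national food supply, using a multiple-cohort proportional
    multistate lifetable (Markov) model. Converts a shift in the population
    trans-fat intake distribution into a potential impact fraction for ischaemic
    heart disease (IHD) incidence, propagates it through an illness-death disease
    model and a cohort lifetable to health-adjusted life years, healthcare and
    policy implementation costs, and summarises cost-effectiveness (ICER, return
    on investment, probability of cost-saving) with probabilistic Monte Carlo
    uncertainty analysis. Includes a generator of internally consistent synthetic
    age-sex-stratified epidemiological inputs in the style of Global Burden of
    Disease exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
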