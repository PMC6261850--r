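Package: worklife
Title: Multistate Working Life Tables from Labor-Market Register Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating working life expectancy (WLE) and related
    state expectancies from annual labor-market register data. Implements a
    discrete-time multistate (Markov chain) life table over four labor-force
    states (employed, unemployed, inactive, retired) plus death, with
    transition probabilities estimated by subsample-split multinomial
    logistic regression with smooth age effects, alignment of aggregate
    mortality to an external period life table, age-band decompositions of
    expectancies and of their change between periods, and prevalence-based
    (Sullivan) expectancies for head-to-head comparison with the
    incidence-based estimates. A seeded synthetic register generator with a
    known ground-truth transition regime makes every stage testable without
    access to confidential register data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
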