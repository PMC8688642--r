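Package: mentholsim
Title: Microsimulation of Cardiovascular Outcomes Under a Menthol
    Cigarette Ban
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Discrete-time microsimulation of myocardial infarction,
    stroke, cardiovascular death and healthcare costs among adult
    cigarette smokers, built to project the 20-year health and economic
    impact of a menthol cigarette sales ban and its effect on sex and
    racial/ethnic disparities.  Provides a configurable
    synthetic-population generator, logistic annual risk equations, a
    policy quit operator evaluated with common random numbers so paired
    scenarios differ only through the policy, age-banded discounted cost
    accounting, replicate-based percentile intervals, and subgroup
    disparity reporting with quit-proportion and discount-rate
    sensitivity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
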