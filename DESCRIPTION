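Package: codqc
Title: Quality Assessment of Mortality and Cause-of-Death Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A ten-step diagnostic assessment of ICD-10-coded death
    tabulations from civil registration and vital statistics systems:
    age-sex structure of deaths and population, death-registration
    completeness (comparator-based and empirical), Gompertz-Makeham
    log-linearity and sex-pattern consistency checks, under-five
    mortality (5q0), usability and broad-cause-group distributions, two
    garbage-code typologies with package extraction, proportional
    garbage redistribution, leading causes with impact flags, and the
    composite Vital Statistics Performance Index for Quality (VSPI(Q))
    with gap attribution. Includes a synthetic-data generator with known
    truth and controllable quality defects so every check is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
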