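Package: aquacpi
Title: Continuous Performance Improvement Assessment for Wastewater
    Treatment Facilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Benchmarking toolkit for the effluent quality of wastewater
    treatment plants under progressively stricter reuse scenarios
    (restricted/unrestricted irrigation, livestock drinking, recreation).
    Implements a grey relational analysis water quality index (GWQI) built
    from rank-based non-exceedance probabilities and Shannon-entropy
    importance weights, and a modified Canadian Council of Ministers of the
    Environment water quality index (CWQI) with a separate microbiological
    sub-index. Includes readers for long-format monitoring data with
    censored (below-detection) values, scenario standards configuration,
    cross-facility benchmarking with gap reporting and improvement-action
    lookup, and a seeded synthetic monitoring-campaign generator calibrated
    to per-facility summary statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
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
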