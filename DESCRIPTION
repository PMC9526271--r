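Package: gsreplay
Title: Group Sequential Designs with Early Longitudinal Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and retrospectively replaying group
    sequential two-arm randomized trials whose primary outcome is a
    patient-reported outcome measure collected repeatedly during follow-up.
    Fits multivariate-normal longitudinal models to incomplete outcome data
    to estimate the treatment effect at the primary time together with its
    statistical information; computes error-spending stopping boundaries by
    recursive numerical integration under the canonical joint distribution
    of sequential test statistics; plans the expected information levels
    that trigger interim analyses from design-stage covariance expectations
    and planned accrual; replays dated trial records in calendar order with
    biweekly information monitoring, futility and efficacy stopping and
    overrunning analyses; and generates fully synthetic dated trials for
    evaluating operating characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
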