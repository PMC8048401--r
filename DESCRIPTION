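Package: homerange
Title: Standardized Estimation of Animal Home Ranges from Telemetry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A common estimator contract for animal home-range estimation from
    GPS relocation data: geometric estimators (minimum convex polygon, k-nearest
    neighbour local convex hulls) and probabilistic estimators (kernel density
    estimation and autocorrelated kernel density estimation driven by
    continuous-time movement models with AICc selection and GPS-error
    calibration), plus home-range overlap indices, grouped batch workflows
    producing tidy long-format tables, exact simulators for testing, and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    grDevices,
    isoband,
    jsonlite,
    lubridate,
    optparse,
    polyclip,
    Rcpp,
    readr,
    rlang,
    sp,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    geosphere,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
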