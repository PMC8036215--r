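Package: deadtime
Title: Interval Distributions for Dead-Time-Modified Poisson Point Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Numerically computes the first-order inter-event and
    inter-detection (interspike) interval distributions expected for an
    inhomogeneous Poisson point process observed through a nonparalyzable
    detector with random dead times, over a finite observation window with
    right censoring. Converts between event and detection rate functions,
    builds forward-recurrence distributions to the next event and the next
    detection, and assembles right-censored interval distributions with
    expected-count normalization. Includes a fast discrete-time Monte Carlo
    simulator and an exhaustive-enumeration oracle for verification, rate
    generators (constant, sinusoid-exponential, random walk), tidy accessors,
    and plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
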