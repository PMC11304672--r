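Package: telesna
Title: Bias and Robustness Assessment for Animal Social Networks from
    GPS Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds proximity-based association networks from GPS
    radio-telemetry relocations using a modified Simple Ratio Index and
    provides a five-step protocol to assess the bias and robustness of
    social network metrics estimated from a partial sample of a
    population: datastream (pre-network) permutation null models,
    node-subsampling bias analysis, bootstrap confidence intervals for
    global and node-level metrics, and correlation/regression stability
    analysis of node metrics between partial and full networks. Includes
    a correlated-random-walk simulator with planted social groups so
    every stage of the protocol can be validated against known structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
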