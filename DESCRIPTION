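Package: incmi
Title: Incremental Mutual Information for Neuronal Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-free, delay-resolved measures of the strength and dynamics
    of the connection between two neurons from binned binary spike trains.
    Implements incremental mutual information (IMI), which conditions out the
    temporal dependencies within each spike train before measuring the
    dependency between them, together with its linear comparators
    (cross-correlation and partial cross-correlation), trial-based signal and
    noise decompositions of both correlation and IMI, quadratic-extrapolation
    bias correction for the underlying entropy estimates, bootstrap confidence
    intervals and shuffle-based significance thresholds, and a dichotomized
    Gaussian simulator of two-neuron circuits for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
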