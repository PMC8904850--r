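Package: epispread
Title: Individualized Seizure-Propagation Modelling and Virtual Resection
    Optimization on Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models seizure propagation as a susceptible-infected (SI)
    epidemic process on weighted, proportionally thresholded brain
    connectivity networks. Fits the network density per patient by rank
    correlation between simulated spreading order and clinically observed
    stereo-EEG activation patterns, and searches for optimal virtual
    resections of a given size using an effective-distance surrogate
    combined with simulated annealing, refined by direct SI simulation.
    Includes an exponential-distance-rule surrogate network generator and
    a synthetic-patient generator so the full pipeline can be exercised
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
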