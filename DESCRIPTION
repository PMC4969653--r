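Package: ph2adapt
Title: Minimax and Admissible Adaptive Two-Stage Designs for Phase II Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact search algorithms for single-arm two-stage phase II trial
    designs with binary endpoints. Implements Simon's minimax and optimal
    designs, the Mander-Thompson design with stage-1 stopping for futility or
    efficacy (minimax-EF), and a minimax adaptive design in which the
    second-stage sample size is a non-increasing function of the number of
    first-stage responses, found by branch-and-bound over conditional error
    functions. Admissible adaptive designs are selected from the lower
    envelope of Bayes risk lines trading off maximum against expected sample
    size. All error rates are exact binomial computations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
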