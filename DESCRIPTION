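Package: putsc
Title: Positive-Unlabeled Time Series Labeling by Self-Training with
    DTW Barycenter Averaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Labels a large unlabeled pool of time series from a small set
    of positive seeds by iterative self-training.  Implements the classic
    one-nearest-neighbour self-training scheme and a barycenter-guided
    variant in which the next series to label is the one closest to the
    DTW barycenter average (DBA) of the current labeled set, together with
    the stopping-criterion-confidence (SCC) rule that cuts the labeling
    trace into positive and negative sets.  Includes unconstrained dynamic
    time warping with squared local costs, DBA and pointwise-Euclidean
    averaging, UCR-format readers and writers, seeded synthetic data
    generators (cylinder-bell-funnel and a boundary-seeded two-class
    scenario), an F1/ranking evaluation harness with repeated random
    initializations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
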