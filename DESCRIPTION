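Package: diapart
Title: Direct Interaction Algorithm for Canonical Partition Functions of
    Two-State Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic O(N^2) approximation of the canonical partition
    function for systems of N pairwise-interacting two-state particles
    (protonation-style microstate models, lattice spin systems). Pairwise
    interactions involving a selected particle are treated exactly through
    elementary symmetric functions, computed by a numerically stable binary
    split-merge convolution tree; the remaining interactions are replaced by
    an average, either globally or per merge step. Includes a 2D Ising test
    bed with a Kaufman-Beale closed-form baseline, small-lattice enumeration
    oracles, a single-flip Metropolis Monte Carlo comparator, and RMS-error
    benchmarking utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
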