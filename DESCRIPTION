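Package: fiberwalk
Title: Fiber Walks: Self-Avoiding Random Walks with Lateral Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates fiber walks, a growing self-avoiding random walk on
    d-dimensional hypercubic lattices in which every elongation step triggers
    a lateral contraction of the lattice, modelling tip-driven growth with
    spatial expansion (e.g. plant root tips). Provides the growing
    self-avoiding walk as the contraction-free special case, reconstruction
    of the closed 2D expansion boundary from the face dual of the lattice
    with an intermediate-lattice refinement, and ensemble statistics:
    stopping-time distributions, mean-square-displacement scaling exponents
    with scaling-region detection and bootstrap errors, contraction-count
    scaling, and edge-length class tallies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
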