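Package: fibernet
Title: Discrete Fiber-Network Mechanics of Cell-Induced Matrix Remodelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-dimensional discrete fiber-network model of extracellular-matrix
    remodelling by contractile cells. Fibers are nonlinear springs on a
    triangulated annular domain with one or two circular cell cavities; two
    constitutive families describe stable (supercritical) and unstable
    (subcritical) post-buckling response in compression. An exponential penalty
    on the oriented-area ratio of each triangular element prevents element
    inversion and interpenetration of matter. Equilibria are computed by
    nonlinear conjugate-gradient minimization of the penalized network energy
    under prescribed cell-boundary contraction, with continuation over
    contraction levels. Post-processing covers densification ratios, fiber
    stretch and orientation distributions, displacement decay-power fits,
    densified-band and intercellular-tether detection, and instability-onset
    detection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    deldir,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
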