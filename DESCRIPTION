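Package: topoqspr
Type: Package
Title: Degree-Based Topological Indices and QSPR Regression for Molecular Graphs
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes six degree-based topological indices (ABC-R, GA, SDD,
    the multiplicative exponential Zagreb indices EPi1 and EPi2, and the
    multiplicative geometric-arithmetic index GAPi) on hydrogen-suppressed
    molecular graphs, with exact log-domain handling of the astronomically
    large exponential indices.  Ships a curated 15-drug study dataset
    (edge-list graphs, physicochemical properties, published descriptor
    values with an errata layer) and fits the quantitative
    structure-property relationship (QSPR) regression families -- linear,
    quadratic and logarithmic -- of each property on each index, returning
    classed model objects with the full set of fit statistics (A, b, c, r,
    r squared, F, p).  Includes a seedable generator of chemical-like
    random graphs and simulated property tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
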