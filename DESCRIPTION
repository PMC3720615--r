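Package: latgrad
Title: Latitudinal Gradients in Species Richness and Assemblage Root Distance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing latitudinal gradients in species richness
    and in the evolutionary "derivedness" of local assemblages, measured as
    mean root distance (MRD): the average number of nodes separating the
    co-occurring species from the root of a phylogeny.  The package grids
    species range polygons onto a 100 x 100 km equal-area lattice, computes
    per-cell richness and MRD, fits penalized-spline smooths of both against
    latitude, diagnoses residual spatial autocorrelation with Moran's I
    correlograms under a Monte-Carlo permutation null, and compares total
    versus basal/derived richness surfaces with Pearson correlations and
    model-II (reduced major axis) regression with one-delete jackknife
    standard errors.  A seeded synthetic-data generator (pure-birth trees,
    rectangular ranges with controllable richness gradients and
    root-distance-latitude coupling) makes the whole pipeline testable
    without proprietary range maps or supertrees.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    mgcv,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
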