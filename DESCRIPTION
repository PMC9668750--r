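Package: perturbmap
Title: Cell Type and Spatial Prioritization of Perturbation Responses
Version: 0.1.0
Authors@R:
    person("perturbmap", "developers", email = "maintainers@perturbmap.dev",
           role = c("aut", "cre"))
Description: Quantifies how transcriptionally separable two experimental
    conditions are, per cell type (random-forest cross-validated AUC over
    balanced subsamples) or per spatial location (the same classifier run in
    k-nearest-neighbour windows over a common coordinate system, yielding an
    AUC map). Includes readers for Matrix Market count triplets and spatial
    positions tables, quality-control filters, a gamma-Poisson spatial
    simulator with ground-truth differential-expression intensity fields for
    validation, two-dimensional locally weighted smoothing of AUC maps, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    optparse,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
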