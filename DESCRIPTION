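Package: grinch
Title: Graph-Regularized Matrix Factorization for Smoothing and TAD
    Calling on Chromatin Contact Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simultaneous smoothing and detection of topologically
    associating domains (TADs) from binned chromatin contact count
    matrices (Hi-C and related assays). Fits a graph-regularized
    non-negative matrix factorization by multiplicative updates from a
    deterministic NNDSVD initialization, converts the factors into
    contiguous clusters with chain-constrained k-medoids, and
    reconstructs a smoothed matrix by low-rank completion. Includes
    mean- and Gaussian-filter baseline smoothers, distance-stratified
    downsampling, a Poisson contact-matrix simulator with planted
    domains, and a suite of TAD evaluation metrics (Davies-Bouldin
    index, delta contact count, Rand index, mutual information,
    boundary fold enrichment, hypergeometric enrichment, Jaccard
    overlap, and area under the precision-recall curve).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
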