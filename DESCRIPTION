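Package: fibercorr
Title: Autocorrelation Analysis of DNA Replication Patterns on Single
    Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of replication patterns measured on stretched single
    DNA molecules (DNA combing, optical mapping). Binarizes replicated
    tracks on each fiber, computes unbiased auto-correlation profiles of
    the binary signals, and fits them together with the initiation-rate
    curve using a one-dimensional Kolmogorov-Johnson-Mehl-Avrami (KJMA)
    nucleation-and-growth model. Replication dynamics can be decomposed
    into a mixture of two independent processes (fast forks with sparse
    initiation versus slow forks with dense initiation), with parameters
    estimated by an island-model genetic algorithm minimizing a reduced
    chi-square. Includes principal component analysis and WPGMA
    hierarchical clustering of profiles with silhouette-based selection of
    the number of clusters, per-fiber classification against the fitted
    processes, and a Monte Carlo lattice simulator of replicating fibers
    that doubles as a synthetic-data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
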