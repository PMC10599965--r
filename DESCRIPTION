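Package: smoothscore
Title: Per-Cell Gene Set Scoring on Neighbor-Graph-Smoothed Single-Cell Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-sample gene set scoring for single-cell RNA-seq count
    matrices. Cells are partitioned by phenotype annotations, a K-nearest
    neighbor graph is built per group in PCA space with a density-adjusted
    Gaussian kernel, and the counts matrix is smoothed by sparse matrix
    multiplication with the graph adjacency (M = AX) before each cell is
    scored against gene sets with a family of single-sample statistics
    (singscore, ssGSEA, rank-biased overlap, summed ranks, mean z-score,
    mean, median, and gene set overlap). Includes a GMT reader with an
    up/down two-part gene set convention, a negative-binomial simulator
    with planted marker genes, binomial count thinning for robustness
    studies, and command-line entry points.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    ggplot2,
    jsonlite,
    methods,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
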