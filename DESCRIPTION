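Package: mgcor
Title: Multiscale Graph Correlation Independence Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Distance-based independence testing that scans k-nearest-neighbor
    restricted distance correlations over all neighborhood scales, takes a
    smoothed maximum over the resulting local-correlation map as its test
    statistic, and derives a p-value by permutation. Includes the unbiased
    (U-centered) and classical distance correlation, Mantel and Gaussian-kernel
    HSIC comparison statistics, a 20-relationship simulation benchmark spanning
    linear, polynomial, trigonometric and geometric dependencies, and a
    Monte-Carlo harness for power estimation and required-sample-size search.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    MASS,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
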