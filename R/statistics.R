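#' Benchmark test statistics
#'
#' Computes one of the implemented dependence statistics from paired samples
#' or from precomputed distance matrices. All are generalized correlations
#' (normalized sums of products of pairwise-comparison matrices):
#'
#' * `mgc`: smoothed maximum over the local-correlation map built on
#'   U-centered Euclidean distances.
#' * `dcorr` / `mcorr` / `mantel`: global correlation of double- / U- /
#'   grand-mean-centered distance matrices.
#' * `hsic`: global correlation of double-centered Gaussian kernel matrices,
#'   with the median-heuristic bandwidth (median off-diagonal distance).
#' * `pearson`: generalized correlation of the centered inner-product
#'   matrices `<x_i - xbar, x_j - xbar>`; equals the squared Pearson
#'   correlation when p = q = 1.
#'
#' @param method one of `"mgc"`, `"dcorr"`, `"mcorr"`, `"mantel"`, `"hsic"`,
#'   `"pearson"`.
#' @param x,y sample matrices; ignored (except for `pearson`) when `dx`, `dy`
#'   are supplied.
#' @param dx,dy optional precomputed distance matrices, to share the distance
#'   computation across statistics.
#' @return scalar test statistic.
#' @export
test_statistic <- function(method, x = NULL, y = NULL, dx = NULL, dy = NULL) {
  method <- match.arg(method, c("mgc", "dcorr", "mcorr", "mantel", "hsic",
                                "pearson"))
  if (method == "pearson") {
    a <- centered_gram(as_sample_matrix(x))
    b <- centered_gram(as_sample_matrix(y))
    return(global_correlation(a, b))
  }
  if (is.null(dx)) dx <- pairwise_distances(as_sample_matrix(x))
  if (is.null(dy)) dy <- pairwise_distances(as_sample_matrix(y))
  switch(method,
    mgc = cpp_mgc_stat_from_dist(dx, dy),
    dcorr = cpp_global_corr_from_dist(dx, dy, 0L),
    mcorr = cpp_global_corr_from_dist(dx, dy, 1L),
    mantel = cpp_global_corr_from_dist(dx, dy, 2L),
    hsic = cpp_global_corr_from_dist(gaussian_kernel(dx),
                                     gaussian_kernel(dy), 0L)
  )
}

# Gaussian kernel matrix from a distance matrix, median-heuristic bandwidth.
# 1 - K is fed through the distance-centering machinery; centering schemes are
# affine-invariant in the matrix entries up to sign, and using 1 - K keeps the
# zero-diagonal/nonnegativity contract of the centering input. The resulting
# generalized correlation is identical to the one computed on K directly.
gaussian_kernel <- function(d) {
  sigma <- stats::median(d[row(d) != col(d)])
  if (sigma <= 0) sigma <- 1
  1 - exp(-d^2 / (2 * sigma^2))
}

centered_gram <- function(x) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  tcrossprod(xc)
}
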