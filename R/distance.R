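#' Pairwise distance matrix
#'
#' Computes the n x n matrix of pairwise distances between the rows of a
#' sample matrix. Rows are observations, columns are features. Euclidean
#' distance is the default throughout the package; squared Euclidean and
#' city-block (L1) are also supported.
#'
#' @param x numeric matrix or vector (a vector is treated as n x 1).
#' @param metric one of `"euclidean"`, `"sqeuclidean"`, `"cityblock"`.
#' @return symmetric numeric matrix with zero diagonal and nonnegative entries.
#' @examples
#' pairwise_distances(matrix(c(0, 3), ncol = 1))
#' @export
pairwise_distances <- function(x, metric = c("euclidean", "sqeuclidean", "cityblock")) {
  metric <- match.arg(metric)
  x <- as_sample_matrix(x)
  d <- switch(metric,
    euclidean  = as.matrix(stats::dist(x, method = "euclidean")),
    sqeuclidean = as.matrix(stats::dist(x, method = "euclidean"))^2,
    cityblock  = as.matrix(stats::dist(x, method = "manhattan"))
  )
  dimnames(d) <- NULL
  attr(d, "metric") <- metric
  d
}

# Validate and coerce an observations-by-features matrix.
as_sample_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1L)
  if (!is.matrix(x) || !is.numeric(x))
    stop("samples must be a numeric matrix (rows = observations)")
  if (!all(is.finite(x)))
    stop("sample matrix contains non-finite entries")
  x
}

check_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square")
  if (!all(is.finite(d)))
    stop("distance matrix contains non-finite entries")
  if (any(d < 0))
    stop("distance matrix has negative entries")
  if (max(abs(d - t(d))) > 1e-8 * max(1, max(abs(d))))
    stop("distance matrix must be symmetric")
  invisible(d)
}

#' Center a distance matrix
#'
#' Applies one of the centering schemes that turn a raw distance matrix into
#' the pairwise-comparison matrix entering a generalized correlation:
#'
#' * `"double"`: classical distance-correlation centering,
#'   `a_ij = d_ij - rowmean_i - colmean_j + grandmean` off the diagonal,
#'   zero on the diagonal.
#' * `"unbiased"`: U-centering behind the unbiased distance correlation;
#'   for `i != j`,
#'   `a_ij = d_ij - colsum_j/(n-2) - rowsum_i/(n-2) + totalsum/((n-1)(n-2))`,
#'   zero on the diagonal. Requires `n >= 3`.
#' * `"mantel"`: subtract the grand mean of the off-diagonal entries, zero
#'   diagonal.
#' * `"single_column"` / `"single_row"`: subtract column means / row means.
#'
#' @param d square distance matrix.
#' @param scheme centering scheme (see Details).
#' @return centered numeric matrix with a `"scheme"` attribute.
#' @export
center_distance_matrix <- function(d,
    scheme = c("unbiased", "double", "mantel", "single_column", "single_row")) {
  scheme <- match.arg(scheme)
  check_distance_matrix(d)
  n <- nrow(d)
  if (scheme == "unbiased" && n < 3)
    stop("unbiased centering requires n >= 3")
  code <- match(scheme,
                c("double", "unbiased", "mantel", "single_column", "single_row")) - 1L
  out <- cpp_center(d, code)
  attr(out, "scheme") <- scheme
  out
}

#' Neighborhood rank matrix
#'
#' Ranks the entries of a distance matrix within each column
#' (`axis = "column"`: entry (i, j) is the rank of observation i among the
#' distances to observation j) or within each row. Rank 1 is always the
#' self-distance, so a neighborhood of size k >= 1 always contains the point
#' itself; remaining ties break by smaller sample index.
#'
#' @param d square distance matrix.
#' @param axis `"column"` or `"row"`.
#' @return integer matrix of ranks in 1..n.
#' @export
rank_distance_matrix <- function(d, axis = c("column", "row")) {
  axis <- match.arg(axis)
  check_distance_matrix(d)
  r <- cpp_rank_matrix(d, byrow = identical(axis, "row"))
  attr(r, "axis") <- axis
  r
}
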