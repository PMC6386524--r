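#' Multiscale graph correlation independence test
#'
#' Tests independence between two paired samples. Pairwise distances are
#' computed within each sample, centered, and the scale-restricted (local)
#' correlations between the two distance structures are scanned over all
#' neighborhood sizes; the smoothed maximum over the resulting map is the test
#' statistic, and significance is assessed by jointly permuting the Y sample.
#'
#' @param x,y numeric matrices (rows = paired observations; a vector is
#'   treated as one column), or n x n distance matrices when
#'   `distance = TRUE`.
#' @param reps number of permutations for the p-value.
#' @param metric distance metric passed to [pairwise_distances()].
#' @param scheme centering scheme; `"unbiased"` (U-centering, the default MGC
#'   transformation), `"double"`, `"mantel"`, or `"single"` (Algorithm-style
#'   single centering: X by column, Y by row).
#' @param seed optional integer seed governing the permutation stream.
#' @param distance logical; inputs are precomputed distance matrices.
#' @return an object of class `"mgc_test"`: statistic, p-value, optimal
#'   scales, local-correlation map, threshold, significant region, and the
#'   call configuration.
#' @examples
#' x <- seq(-1, 1, length.out = 20)
#' out <- mgc_test(x, 2 * x + 3, reps = 99, seed = 1)
#' out$statistic   # 1: distances are preserved up to scale
#' @export
mgc_test <- function(x, y, reps = 999,
                     metric = c("euclidean", "sqeuclidean", "cityblock"),
                     scheme = c("unbiased", "double", "mantel", "single"),
                     seed = NULL, distance = FALSE) {
  metric <- match.arg(metric)
  scheme <- match.arg(scheme)
  if (distance) {
    dx <- as.matrix(x); dy <- as.matrix(y)
    check_distance_matrix(dx); check_distance_matrix(dy)
  } else {
    x <- as_sample_matrix(x); y <- as_sample_matrix(y)
    if (nrow(x) != nrow(y))
      stop("x and y must have the same number of observations")
    dx <- pairwise_distances(x, metric)
    dy <- pairwise_distances(y, metric)
  }
  n <- nrow(dx)
  if (n != nrow(dy)) stop("x and y must have the same number of observations")
  if (n < 4) stop("MGC test requires n >= 4")
  scheme_x <- if (scheme == "single") "single_column" else scheme
  scheme_y <- if (scheme == "single") "single_row" else scheme
  a <- center_distance_matrix(dx, scheme_x)
  b <- center_distance_matrix(dy, scheme_y)
  ranks_a <- rank_distance_matrix(dx, "column")
  ranks_b <- rank_distance_matrix(dy, "row")
  st <- mgc_statistic(a, b, ranks_a, ranks_b)
  if (!is.null(seed)) set.seed(seed)
  pt <- mgc_permutation_test(a, b, ranks_a, ranks_b, reps = reps,
                             statistic = st$statistic)
  structure(list(
    statistic = st$statistic,
    p_value = pt$p_value,
    optimal_scales = st$optimal_scales,
    scale = st$optimal_scales[1, ],
    map = st$map,
    tau = st$tau,
    region_size = st$region$size,
    smoothed = st$smoothed,
    n = n,
    reps = reps,
    seed = seed,
    metric = metric,
    scheme = scheme
  ), class = "mgc_test")
}

#' @export
print.mgc_test <- function(x, ...) {
  cat("\tMultiscale graph correlation test of independence\n\n")
  cat(sprintf("n = %d, metric = %s, centering = %s\n", x$n, x$metric, x$scheme))
  cat(sprintf("MGC statistic = %.6g, p-value = %.6g (%d permutations)\n",
              x$statistic, x$p_value, x$reps))
  cat(sprintf("optimal scale (k, l) = (%d, %d)%s\n", x$scale[1], x$scale[2],
              if (x$scale[1] == x$n && x$scale[2] == x$n) " [global]" else " [local]"))
  cat(sprintf("threshold tau = %.4g, significant region = %d scales\n",
              x$tau, x$region_size))
  invisible(x)
}
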