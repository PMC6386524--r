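#' Significance threshold for a local-correlation map
#'
#' The threshold above which a local correlation is considered significant:
#' 3.5 times the mean square of the negative map entries (a proxy for the null
#' fluctuation scale, floored at 0.01), but never below 2/n nor below the
#' global correlation (map entry (n, n)). With no negative entries the
#' fluctuation term is 0.
#'
#' @param cmap n x n local-correlation map.
#' @return scalar threshold.
#' @export
mgc_threshold <- function(cmap) {
  stopifnot(is.matrix(cmap), nrow(cmap) == ncol(cmap))
  cpp_threshold(cmap)
}

#' Largest connected region of significant scales
#'
#' Thresholds the map at `tau` and extracts the largest 8-connected component
#' of `{(k, l): c_kl > tau}`.
#'
#' @param cmap n x n local-correlation map.
#' @param tau threshold; defaults to [mgc_threshold()].
#' @return list with `mask` (logical n x n), `tau`, and `size` (number of
#'   scales in the component; 0 when nothing exceeds the threshold).
#' @export
mgc_significant_region <- function(cmap, tau = mgc_threshold(cmap)) {
  stopifnot(is.matrix(cmap), nrow(cmap) == ncol(cmap), is.finite(tau))
  mask <- cpp_largest_component(cmap, tau)
  list(mask = mask, tau = tau, size = sum(mask))
}

#' MGC statistic from centered matrices
#'
#' Computes the local-correlation map and takes its smoothed maximum: the
#' statistic defaults to the global correlation c_nn, unless the largest
#' connected component of significant scales covers at least 2n scales, in
#' which case the statistic is the maximum local correlation inside that
#' component. The optimal scales are all scales attaining the statistic (the
#' global scale (n, n) when defaulting), with the lexicographically smallest
#' pair reported first.
#'
#' @param a,b centered n x n matrices (n >= 4).
#' @param ranks_a,ranks_b column-axis / row-axis rank matrices; computed from
#'   `a`, `b` only via the distance matrices, so they must be supplied.
#' @return list with `statistic`, `optimal_scales` (m x 2 integer matrix of
#'   (k, l) pairs), `map`, `tau`, `region` (as in [mgc_significant_region()]),
#'   and `smoothed` (TRUE when the non-default branch was taken).
#' @export
mgc_statistic <- function(a, b, ranks_a, ranks_b) {
  n <- nrow(a)
  if (n < 4) stop("MGC statistic requires n >= 4")
  res <- cpp_mgc_sample_stat(a, b, storage_int(ranks_a), storage_int(ranks_b))
  cmap <- res$map
  smoothed <- res$region_size >= 2 * n && !(res$k == n && res$l == n)
  mask <- cpp_largest_component(cmap, res$tau)
  if (res$region_size >= 2 * n) {
    cand <- which(mask & abs(cmap - res$statistic) <= 1e-12, arr.ind = TRUE)
  } else {
    cand <- matrix(c(n, n), ncol = 2)
  }
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  dimnames(cand) <- list(NULL, c("k", "l"))
  list(statistic = res$statistic,
       optimal_scales = cand,
       map = cmap,
       tau = res$tau,
       region = list(mask = mask, tau = res$tau, size = res$region_size),
       smoothed = smoothed)
}

# Centered matrices + ranks from a raw distance matrix, the common
# preprocessing for the MGC pipeline.
mgc_prepare <- function(d, scheme = "unbiased") {
  list(a = center_distance_matrix(d, scheme),
       ranks_col = rank_distance_matrix(d, "column"),
       ranks_row = rank_distance_matrix(d, "row"))
}

#' Permutation p-value for the MGC statistic
#'
#' Jointly permutes rows and columns of the Y-side matrices and recomputes the
#' full statistic pipeline (map, threshold, region, smoothed maximum) for each
#' permutation. The p-value uses the add-one correction
#' `p = (1 + #\{c*_perm >= c*\}) / (r + 1)`, which is never exactly 0.
#'
#' @param a,b centered matrices for X and Y.
#' @param ranks_a column-axis ranks of the X distances.
#' @param ranks_b row-axis ranks of the Y distances.
#' @param reps number of permutations r >= 1.
#' @param statistic observed statistic; recomputed when missing.
#' @return list with `p_value`, `statistic`, and the vector `null_stats`.
#' @export
mgc_permutation_test <- function(a, b, ranks_a, ranks_b, reps = 999,
                                 statistic = NULL) {
  if (reps < 1) stop("number of permutations must be >= 1")
  n <- nrow(a)
  if (is.null(statistic))
    statistic <- mgc_statistic(a, b, ranks_a, ranks_b)$statistic
  perms <- t(vapply(seq_len(reps), function(i) sample.int(n), integer(n)))
  null_stats <- cpp_permuted_stats(a, b, storage_int(ranks_a),
                                   storage_int(ranks_b), perms)
  p <- (1 + sum(null_stats >= statistic)) / (reps + 1)
  list(p_value = p, statistic = statistic, null_stats = null_stats)
}
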