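#' Global generalized correlation of two centered matrices
#'
#' The generalized correlation `sum(a_ij * b_ij) / (n^2 sigma_a sigma_b)`,
#' computed as the Pearson correlation of the n^2 entries of `a` against the
#' n^2 entries of `b`. With double-centered inputs this is the (biased sample)
#' distance correlation; with U-centered inputs the unbiased variant; with
#' Mantel centering the Mantel statistic. Returns 0 when either matrix has
#' zero entry variance.
#'
#' @param a,b centered n x n matrices (same n).
#' @return scalar in \[-1, 1\].
#' @export
global_correlation <- function(a, b) {
  if (!is.matrix(a) || !is.matrix(b) || any(dim(a) != dim(b)) ||
      nrow(a) != ncol(a))
    stop("centered matrices must be square and of equal size")
  cpp_global_correlation(a, b)
}

#' Local generalized correlation at one scale
#'
#' Restricts the generalized correlation to the (k, l) neighborhood: entries
#' a_ij with rank(i within column j) <= k and b_ij with rank(j within row i)
#' <= l are kept, all others set to zero, and the Pearson-style normalization
#' is taken over all n^2 positions. This direct per-scale computation is
#' O(n^2) per scale; use [local_correlation_map()] for all scales at once.
#'
#' @param a,b centered n x n matrices.
#' @param ranks_a column-axis rank matrix of the X distances.
#' @param ranks_b row-axis rank matrix of the Y distances.
#' @param k,l neighborhood sizes in 1..n.
#' @return scalar local correlation c_kl in \[-1, 1\] (0 at zero-variance scales).
#' @export
local_correlation <- function(a, b, ranks_a, ranks_b, k, l) {
  n <- nrow(a)
  if (k < 1 || k > n || l < 1 || l > n)
    stop("scale (k, l) must lie in 1..n")
  ak <- a * (ranks_a <= k)
  bl <- b * (ranks_b <= l)
  n2 <- n * n
  va <- sum(ak * ak) - sum(ak)^2 / n2
  vb <- sum(bl * bl) - sum(bl)^2 / n2
  if (va <= 0 || vb <= 0) return(0)
  (sum(ak * bl) - sum(ak) * sum(bl) / n2) / sqrt(va * vb)
}

#' Local-correlation map (all scales)
#'
#' Computes the full n x n grid of local generalized correlations c_kl for
#' k, l = 1..n in O(n^2) after ranking, by depositing each product a_ij b_ij
#' at its rank pair and accumulating prefix sums. Entry (n, n) equals the
#' global correlation of `a` and `b`.
#'
#' @inheritParams local_correlation
#' @return n x n numeric matrix; rows index the X neighborhood size k, columns
#'   the Y neighborhood size l.
#' @export
local_correlation_map <- function(a, b, ranks_a, ranks_b) {
  if (any(dim(a) != dim(b)) || any(dim(a) != dim(ranks_a)) ||
      any(dim(a) != dim(ranks_b)))
    stop("inputs must all be n x n")
  cpp_local_correlation_map(a, b, storage_int(ranks_a), storage_int(ranks_b))
}

storage_int <- function(m) {
  storage.mode(m) <- "integer"
  m
}
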