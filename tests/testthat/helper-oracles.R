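# Independent oracles, coded directly from the definitions and kept free of
# any package internals.

# Brute-force pairwise distances by explicit double loop.
oracle_distances <- function(x, metric = "euclidean") {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      diff <- x[i, ] - x[j, ]
      d[i, j] <- switch(metric,
        euclidean = sqrt(sum(diff^2)),
        sqeuclidean = sum(diff^2),
        cityblock = sum(abs(diff)))
    }
  }
  d
}

# Textbook U-centering, written entry by entry.
oracle_ucenter <- function(d) {
  n <- nrow(d)
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        a[i, j] <- d[i, j] - sum(d[, j]) / (n - 2) - sum(d[i, ]) / (n - 2) +
          sum(d) / ((n - 1) * (n - 2))
      }
    }
  }
  a
}

# Double centering with zeroed diagonal, written entry by entry.
oracle_dcenter <- function(d) {
  n <- nrow(d)
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        a[i, j] <- d[i, j] - mean(d[i, ]) - mean(d[, j]) + mean(d)
      }
    }
  }
  a
}

# Local correlation at scale (k, l) as the plain Pearson correlation of the
# two n^2-vectors with out-of-neighborhood entries zeroed.
oracle_local_corr <- function(a, b, ra, rb, k, l) {
  av <- as.vector(a * (ra <= k))
  bv <- as.vector(b * (rb <= l))
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(0)
  val <- stats::cor(av, bv)
  if (!is.finite(val)) 0 else val
}

# Largest 8-connected component of a logical matrix via igraph.
oracle_largest_component <- function(mask) {
  n <- nrow(mask)
  idx <- which(mask)
  out <- matrix(FALSE, n, n)
  if (length(idx) == 0) return(out)
  coord <- arrayInd(idx, dim(mask))
  edges <- integer(0)
  for (u in seq_along(idx)) {
    for (v in seq_along(idx)) {
      if (u < v && max(abs(coord[u, ] - coord[v, ])) <= 1) {
        edges <- c(edges, u, v)
      }
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  out[idx[keep]] <- TRUE
  out
}

# Standard preprocessing bundle used across tests.
prep_pair <- function(x, y, scheme = "unbiased") {
  dx <- pairwise_distances(x)
  dy <- pairwise_distances(y)
  list(
    a = center_distance_matrix(dx, scheme),
    b = center_distance_matrix(dy, scheme),
    ra = rank_distance_matrix(dx, "column"),
    rb = rank_distance_matrix(dy, "row"),
    dx = dx, dy = dy
  )
}

# 2-D rotation matrix.
rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}
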