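test_that("pairwise distances match a brute-force double loop for all metrics", {
  set.seed(42)
  x <- matrix(rnorm(10), 5, 2)
  for (metric in c("euclidean", "sqeuclidean", "cityblock")) {
    d <- pairwise_distances(x, metric)
    expect_equal(d, oracle_distances(x, metric), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0))
  }
  # 1-D pair at 0 and 3
  expect_equal(pairwise_distances(c(0, 3))[1, 2], 3)
  # single observation
  expect_equal(pairwise_distances(matrix(1.5, 1, 1)), matrix(0, 1, 1),
               ignore_attr = TRUE)
})

test_that("Euclidean distances are invariant to translation and rotation", {
  set.seed(7)
  x <- matrix(rnorm(16), 8, 2)
  d0 <- pairwise_distances(x)
  shifted <- sweep(x, 2, c(3, -11), "+")
  rotated <- x %*% rot2(0.83)
  expect_equal(pairwise_distances(shifted), d0, tolerance = 1e-10)
  expect_equal(pairwise_distances(rotated), d0, tolerance = 1e-10)
})

test_that("distance input validation catches bad inputs", {
  expect_error(pairwise_distances(matrix(c(1, NA), 2, 1)), "non-finite")
  expect_error(mgc_test(1:3, 1:4), "same number|n >= 4")
})

test_that("double centering matches the hand formula and kills constants", {
  # direct evaluation on the 2x2 exchange matrix
  expect_equal(center_distance_matrix(matrix(c(0, 1, 1, 0), 2), "double"),
               matrix(c(0, 0.5, 0.5, 0), 2), ignore_attr = TRUE)
  # mutually equidistant points: the zero diagonal enters the means, so the
  # off-diagonal residue is c/n rather than 0
  d <- matrix(4, 6, 6); diag(d) <- 0
  cd <- center_distance_matrix(d, "double")
  off <- row(d) != col(d)
  expect_equal(unname(cd[off]), rep(4 / 6, 30), tolerance = 1e-12)
  # while a fully constant comparison matrix is annihilated outright
  expect_equal(max(abs(center_distance_matrix(matrix(0, 6, 6), "double") +
                         oracle_dcenter(matrix(0, 6, 6)))), 0)
  # entrywise oracle on random input
  set.seed(1)
  d <- pairwise_distances(matrix(rnorm(12), 6, 2))
  expect_equal(center_distance_matrix(d, "double"), oracle_dcenter(d),
               tolerance = 1e-12, ignore_attr = TRUE)
  # row/column sums of the full double-centered projection vanish
  n <- 6
  rm <- rowMeans(d); cm <- colMeans(d)
  proj <- d - outer(rm, rep(1, n)) - outer(rep(1, n), cm) + mean(d)
  expect_lt(max(abs(rowSums(proj))), 1e-10)
  expect_lt(max(abs(colSums(proj))), 1e-10)
})

test_that("U-centering matches an independently coded textbook version", {
  set.seed(2)
  d <- pairwise_distances(matrix(rnorm(18), 6, 3))
  a <- center_distance_matrix(d, "unbiased")
  expect_equal(a, oracle_ucenter(d), tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(diag(a) == 0))
  # U-centered off-diagonal row sums vanish
  expect_lt(max(abs(rowSums(a))), 1e-10)
  expect_error(center_distance_matrix(pairwise_distances(c(0, 1)), "unbiased"),
               "n >= 3")
})

test_that("mantel and single-axis centering schemes follow their definitions", {
  set.seed(3)
  d <- pairwise_distances(matrix(rnorm(10), 5, 2))
  m <- center_distance_matrix(d, "mantel")
  off <- row(d) != col(d)
  expect_equal(m[off], d[off] - mean(d[off]), tolerance = 1e-12)
  expect_true(all(diag(m) == 0))
  sc <- center_distance_matrix(d, "single_column")
  expect_lt(max(abs(colSums(sc))), 1e-10)
  sr <- center_distance_matrix(d, "single_row")
  expect_lt(max(abs(rowSums(sr))), 1e-10)
})

test_that("rank matrices put self first, are column permutations, and are monotone-invariant", {
  # hand-ordered 1-D example: points 0, 1, 3
  d <- pairwise_distances(c(0, 1, 3))
  r <- rank_distance_matrix(d, "column")
  expect_equal(r[, 1], c(1L, 2L, 3L), ignore_attr = TRUE)
  expect_equal(rank_distance_matrix(matrix(0, 1, 1), "column")[1, 1], 1L)
  set.seed(4)
  d <- pairwise_distances(matrix(rnorm(24), 12, 2))
  rc <- rank_distance_matrix(d, "column")
  for (j in 1:12) {
    expect_setequal(rc[, j], 1:12)
    expect_equal(rc[j, j], 1L)
  }
  rr <- rank_distance_matrix(d, "row")
  expect_equal(rr[3, ], rc[, 3], ignore_attr = TRUE) # symmetric distances
  # strictly monotone transform of the distances leaves ranks unchanged
  d2 <- sqrt(d) + d^2
  expect_equal(rank_distance_matrix(d2, "column"), rc, ignore_attr = TRUE)
})

test_that("rank ties break deterministically by sample index", {
  # three collinear points where two are equidistant from the center one
  d <- pairwise_distances(c(0, 1, 2))
  r <- rank_distance_matrix(d, "column")
  # column 2: self first, then observations 1 and 3 tie -> index order
  expect_equal(r[, 2], c(2L, 1L, 3L), ignore_attr = TRUE)
})
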