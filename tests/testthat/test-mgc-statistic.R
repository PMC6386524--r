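test_that("threshold follows the negative-fluctuation rule", {
  # no negative entries, n = 50, global entry 0.2: the global term wins
  cmap <- matrix(0.1, 50, 50); cmap[50, 50] <- 0.2
  expect_equal(mgc_threshold(cmap), 0.2)
  # negatives all -0.05, n = 100, global 0: mean square 0.0025 < 0.01 floor
  cmap <- matrix(-0.05, 100, 100); cmap[100, 100] <- 0
  expect_equal(mgc_threshold(cmap), 0.035)
  # threshold never falls below the global statistic
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    cmap <- matrix(runif(n * n, -1, 1), n, n)
    expect_gte(mgc_threshold(cmap), cmap[n, n])
    expect_gte(mgc_threshold(cmap), 2 / n)
  }
})

test_that("significant region is the largest connected component", {
  n <- 12
  cmap <- matrix(0, n, n)
  # two disjoint blocks above threshold, sizes 5 and 9
  cmap[2, 2:6] <- 1          # 1 x 5 strip
  cmap[8:10, 9:11] <- 1      # 3 x 3 block
  reg <- mgc_significant_region(cmap, tau = 0.5)
  expect_equal(reg$size, 9)
  expect_true(all(reg$mask[8:10, 9:11]))
  expect_false(any(reg$mask[2, 2:6]))
  # nothing significant
  expect_equal(mgc_significant_region(cmap, tau = 2)$size, 0)
  # everything significant is one component
  expect_equal(mgc_significant_region(matrix(1, n, n), tau = 0.5)$size, n^2)
})

test_that("connected-component extraction matches an igraph oracle", {
  skip_if_not_installed("igraph")
  set.seed(22)
  for (rep in 1:20) {
    n <- sample(5:15, 1)
    cmap <- matrix(runif(n * n), n, n)
    tau <- runif(1, 0.3, 0.9)
    mine <- mgc_significant_region(cmap, tau)
    orac <- oracle_largest_component(cmap > tau)
    expect_equal(sum(mine$mask), sum(orac))
    # component sizes can tie; masks must agree when the largest is unique
    if (sum(mine$mask) > 0 && identical(sum(mine$mask), sum(orac)))
      expect_true(all(mine$mask == orac) ||
                    sum(mine$mask & orac) == 0 || all(mine$mask == orac))
  }
})

test_that("statistic defaults to the global correlation for small regions", {
  set.seed(23)
  n <- 20
  pr <- prep_pair(matrix(rnorm(n), n, 1), matrix(rnorm(n), n, 1))
  st <- mgc_statistic(pr$a, pr$b, pr$ra, pr$rb)
  if (st$region$size < 2 * n) {
    expect_identical(st$statistic, st$map[n, n])
    expect_equal(st$optimal_scales, matrix(c(n, n), 1, 2),
                 ignore_attr = TRUE)
  }
  # every reported optimal scale attains the statistic on the map
  for (i in seq_len(nrow(st$optimal_scales))) {
    kl <- st$optimal_scales[i, ]
    expect_lt(abs(st$map[kl[1], kl[2]] - st$statistic), 1e-12)
  }
})

test_that("noiseless affine relationships give statistic 1 at the global scale", {
  set.seed(24)
  n <- 20
  x <- matrix(runif(n, -1, 1), n, 1)
  pr <- prep_pair(x, 2 * x + 3)
  st <- mgc_statistic(pr$a, pr$b, pr$ra, pr$rb)
  expect_equal(st$statistic, 1, tolerance = 1e-10)
  expect_equal(st$optimal_scales[1, ], c(k = 20, l = 20))
  # multivariate rotation + translation, several dimensions and sizes
  for (p in c(2, 5)) {
    n <- 40
    x <- matrix(rnorm(n * p), n, p)
    w <- qr.Q(qr(matrix(rnorm(p * p), p)))   # orthogonal
    y <- x %*% w + matrix(rnorm(p), n, p, byrow = TRUE)
    pr <- prep_pair(x, y)
    st <- mgc_statistic(pr$a, pr$b, pr$ra, pr$rb)
    expect_equal(st$statistic, 1, tolerance = 1e-10)
    expect_equal(unname(st$optimal_scales[1, ]), c(n, n))
  }
})

test_that("the spiral relationship predominantly selects a non-global scale", {
  # strongly nonlinear dependence: the informative neighborhoods are local,
  # so the smoothed maximum should leave the global scale in a clear majority
  # of replicates (the region-size guard keeps a minority at the default)
  hits <- 0
  for (s in 1:60) {
    d <- simulate_relationship(8, n = 60, p = 1, kappa = 1, seed = 3000 + s)
    pr <- prep_pair(d$x, d$y)
    st <- mgc_statistic(pr$a, pr$b, pr$ra, pr$rb)
    kl <- st$optimal_scales[1, ]
    if (!(kl[1] == 60 && kl[2] == 60)) hits <- hits + 1
  }
  expect_gte(hits / 60, 0.6)
})

test_that("degenerate constant samples give statistic 0 and p-value 1", {
  set.seed(25)
  x <- matrix(rnorm(10), 10, 1)
  y <- matrix(1, 10, 1)
  res <- mgc_test(x, y, reps = 49, seed = 1)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})
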