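#' Decaying dimension weights
#'
#' Weight vector `w[d] = 1/d` used to combine the dimensions of X in the
#' high-dimensional simulations, so that each added dimension carries less
#' signal.
#'
#' @param p number of dimensions, `p >= 1`.
#' @return numeric vector `c(1, 1/2, ..., 1/p)`.
#' @export
decay_weights <- function(p) {
  if (!is.numeric(p) || length(p) != 1 || p < 1 || p != round(p))
    stop("p must be a positive integer")
  1 / seq_len(p)
}

#' Catalog of the simulated dependence relationships
#'
#' @return data frame with columns `type` (1..20), `name`, `q_rule`
#'   (`"p"` when the Y dimension equals p, else `"1"`), and `group`
#'   (`"monotone"` for types 1-5, `"non-monotone"` for 6-19,
#'   `"independent"` for 20).
#' @export
simulation_types <- function() {
  qp <- c(4, 10, 12, 13, 14, 18, 19, 20)
  data.frame(
    type = 1:20,
    name = c("linear", "exponential", "cubic", "joint_normal", "step",
             "quadratic", "w_shape", "spiral", "uncorrelated_bernoulli",
             "logarithmic", "fourth_root", "sine_4pi", "sine_16pi", "square",
             "two_parabolas", "circle", "ellipse", "diamond",
             "multiplicative_noise", "multimodal_independence"),
    q_rule = ifelse(1:20 %in% qp, "p", "1"),
    group = c(rep("monotone", 5), rep("non-monotone", 14), "independent"),
    stringsAsFactors = FALSE
  )
}

runif_mat <- function(n, p, lo, hi) matrix(stats::runif(n * p, lo, hi), n, p)
rnorm_mat <- function(n, p) matrix(stats::rnorm(n * p), n, p)

#' Sample one of the 20 dependence relationships
#'
#' Draws n paired observations (X, Y) from the requested relationship. The
#' noise level `kappa` scales every noise term added to Y; noise terms that
#' are part of the construction of X (e.g. the jitter placing points around
#' the circle, square, or sine carrier) are intrinsic to the marginal of X and
#' are not scaled. The Y dimension is `q = p` for types 4, 10, 12, 13, 14, 18,
#' 19, 20 and `q = 1` otherwise.
#'
#' @param type integer 1..20 (see [simulation_types()]).
#' @param n sample size.
#' @param p dimension of X.
#' @param kappa noise scalar; defaults to 1 when `p = 1` and 0 otherwise (the
#'   one- and high-dimensional benchmark conventions).
#' @param seed optional integer seed; identical specs give identical draws.
#' @return list with `x` (n x p), `y` (n x q), `type`, `n`, `p`, `q`, `kappa`.
#' @examples
#' d <- simulate_relationship(8, n = 60, p = 1, seed = 7)  # noisy spiral
#' @export
simulate_relationship <- function(type, n, p = 1,
                                  kappa = if (p == 1) 1 else 0,
                                  seed = NULL) {
  if (!type %in% 1:20) stop("unknown relationship type: ", type)
  if (n < 1) stop("n must be positive")
  if (!is.null(seed)) set.seed(seed)
  w <- decay_weights(p)
  xw <- function(x) drop(x %*% w)
  eps <- function(q = 1) rnorm_mat(n, q)
  x <- NULL; y <- NULL
  switch(as.character(type),
    "1" = { # linear
      x <- runif_mat(n, p, -1, 1)
      y <- cbind(xw(x) + kappa * eps())
    },
    "2" = { # exponential
      x <- runif_mat(n, p, 0, 3)
      y <- cbind(exp(xw(x)) + 10 * kappa * eps())
    },
    "3" = { # cubic
      x <- runif_mat(n, p, -1, 1)
      z <- xw(x) - 1 / 3
      y <- cbind(128 * z^3 + 48 * z^2 - 12 * z + 80 * kappa * eps())
    },
    "4" = { # joint normal
      rho <- 1 / (2 * p)
      sigma <- rbind(cbind(diag(p), rho * matrix(1, p, p)),
                     cbind(rho * matrix(1, p, p), (1 + 0.5 * kappa) * diag(p)))
      xy <- MASS::mvrnorm(n, mu = rep(0, 2 * p), Sigma = sigma)
      xy <- matrix(xy, nrow = n)
      x <- xy[, seq_len(p), drop = FALSE]
      y <- xy[, p + seq_len(p), drop = FALSE]
    },
    "5" = { # step
      x <- runif_mat(n, p, -1, 1)
      y <- cbind((xw(x) > 0) + kappa * eps())
    },
    "6" = { # quadratic
      x <- runif_mat(n, p, -1, 1)
      y <- cbind(xw(x)^2 + 0.5 * kappa * eps())
    },
    "7" = { # w shape
      u <- runif_mat(n, p, -1, 1)
      x <- runif_mat(n, p, -1, 1)
      y <- cbind(4 * ((xw(x)^2 - 0.5)^2 + xw(u) / 500) + 0.5 * kappa * eps())
    },
    "8" = { # spiral
      u <- stats::runif(n, 0, 5)
      x <- matrix(0, n, p)
      if (p > 1)
        for (d in seq_len(p - 1))
          x[, d] <- u * sin(pi * u) * cos(pi * u)^d
      x[, p] <- u * cos(pi * u)^p
      y <- cbind(u * sin(pi * u) + 0.4 * p * kappa * eps())
    },
    "9" = { # uncorrelated bernoulli
      u <- stats::rbinom(n, 1, 0.5)
      x <- matrix(stats::rbinom(n * p, 1, 0.5), n, p) + 0.5 * rnorm_mat(n, p)
      y <- cbind((2 * u - 1) * xw(x) + 0.5 * kappa * eps())
    },
    "10" = { # logarithmic
      x <- rnorm_mat(n, p)
      y <- 2 * log2(abs(x)) + 3 * kappa * eps(p)
    },
    "11" = { # fourth root
      x <- runif_mat(n, p, -1, 1)
      y <- cbind(abs(xw(x))^(1 / 4) + kappa / 4 * eps())
    },
    "12" = , # sine, period 4 pi
    "13" = { # sine, period 16 pi
      theta <- if (type == 12) 4 * pi else 16 * pi
      coef <- if (type == 12) 1 else 0.5
      u <- stats::runif(n, -1, 1)
      v <- rnorm_mat(n, p)
      x <- u + 0.02 * p * v
      y <- sin(theta * x) + coef * kappa * eps(p)
    },
    "14" = , # square
    "18" = { # diamond
      theta <- if (type == 14) -pi / 8 else -pi / 4
      u <- stats::runif(n, -1, 1)
      v <- stats::runif(n, -1, 1)
      e <- rnorm_mat(n, p)
      x <- u * cos(theta) + v * sin(theta) + 0.05 * p * e
      y <- matrix(-u * sin(theta) + v * cos(theta), n, p)
    },
    "15" = { # two parabolas
      e <- stats::runif(n, 0, 1)
      u <- stats::rbinom(n, 1, 0.5)
      x <- runif_mat(n, p, -1, 1)
      y <- cbind((xw(x)^2 + 2 * kappa * e) * (u - 0.5))
    },
    "16" = , # circle
    "17" = { # ellipse
      r <- if (type == 16) 1 else 5
      u <- runif_mat(n, p, -1, 1)
      e <- rnorm_mat(n, p)
      x <- matrix(0, n, p)
      if (p > 1)
        for (d in seq_len(p - 1)) {
          prodcos <- apply(cos(pi * u[, seq_len(d), drop = FALSE]), 1, prod)
          x[, d] <- r * (sin(pi * u[, d + 1]) * prodcos + 0.4 * e[, d])
        }
      x[, p] <- r * (apply(cos(pi * u), 1, prod) + 0.4 * e[, p])
      y <- cbind(sin(pi * u[, 1]))
    },
    "19" = { # multiplicative noise
      u <- rnorm_mat(n, p)
      x <- rnorm_mat(n, p)
      y <- u * x
    },
    "20" = { # multimodal independence
      u <- rnorm_mat(n, p); v <- rnorm_mat(n, p)
      ub <- matrix(stats::rbinom(n * p, 1, 0.5), n, p)
      vb <- matrix(stats::rbinom(n * p, 1, 0.5), n, p)
      x <- u / 3 + 2 * ub - 1
      y <- v / 3 + 2 * vb - 1
    }
  )
  list(x = x, y = y, type = type, n = n, p = p, q = ncol(y), kappa = kappa)
}
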