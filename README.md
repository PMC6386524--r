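# mgcor

Multiscale graph correlation (MGC) independence testing for paired samples of
arbitrary dimension, with the simulation benchmark and Monte-Carlo power
harness used to evaluate it.

## The problem and the statistic

Given paired observations $(x_i, y_i) \in \mathbb{R}^p \times \mathbb{R}^q$,
the package tests $H_0: F_{XY} = F_X F_Y$. Distance correlation and its
relatives correlate the entries of centered pairwise-distance matrices $A$
and $B$:

$$c = \frac{1}{n^2 \sigma_a \sigma_b} \sum_{i,j} a_{ij} b_{ij},$$

a *generalized correlation* in $[-1, 1]$. Global statistics of this form lose
power on nonlinear relationships, where only the short distances are
informative. MGC restricts the sum to $k$-nearest-neighbor entries of $A$ and
$l$-nearest-neighbor entries of $B$, producing a *local correlation*
$c_{kl}$ at every scale $(k, l)$. The $n \times n$ grid of local correlations
(the map) characterizes the geometry of the dependence; the MGC statistic

$$c^* = \max_{(k,l) \in \mathcal{R}} c_{kl}, \qquad
\mathcal{R} = \text{largest connected component of } \{(k,l): c_{kl} > \tau\},$$

is a *smoothed* maximum: it defaults to the global correlation $c_{nn}$
unless the significant region $\mathcal{R}$ spans at least $2n$ scales. The
threshold $\tau$ is estimated from the negative map entries. A permutation
test that recomputes the whole pipeline per permutation gives a valid
p-value with the scale selection inside the inference loop. For affine
relationships the optimal scale is provably global with statistic 1; a local
optimal scale indicates a nonlinear dependence.

The local-correlation map for all $n^2$ scales is computed in $O(n^2)$ after
ranking (a cumulative-sum recursion implemented in C++), so the full test
costs $O(n^2 (\log n + r))$ for $r$ permutations.

## Worked example

```r
library(mgcor)

d <- simulate_relationship(8, n = 100, p = 1, kappa = 1, seed = 7)  # noisy spiral
res <- mgc_test(d$x, d$y, reps = 999, seed = 1)
res
#>         Multiscale graph correlation test of independence
#>
#> n = 100, metric = euclidean, centering = unbiased
#> MGC statistic = 0.0661065, p-value = 0.005 (999 permutations)
#> optimal scale (k, l) = (3, 5) [local]
#> threshold tau = 0.035, significant region = 638 scales
```

The statistic is the largest local correlation inside the significant region
(0.066 at neighborhood sizes 3 and 5 — far from the global corner, the
signature of a strongly nonlinear relationship), and the p-value is the
add-one permutation estimate. An affine pair instead gives statistic 1 at the global scale
(k, l) = (n, n):

```r
x <- matrix(runif(20, -1, 1), ncol = 1)
mgc_test(x, 2 * x + 3, reps = 99, seed = 1)$statistic
#> [1] 1
```

The twenty benchmark relationships (linear through multimodal independence)
are available via `simulate_relationship()`, Monte-Carlo power via
`estimate_power()`, and the required-sample-size search and ratio tables via
`required_sample_size()` and `median_sample_size_ratios()`. A thin
command-line front end ships in `exec/mgc` with subcommands `test`, `map`,
`simulate`, `power`, and `fixture`.

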