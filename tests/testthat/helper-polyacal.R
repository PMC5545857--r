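# Shared fixtures and independent oracles, all built in code.

# Gaussian class samples with mean separation delta.
gaussian_samples <- function(n1 = 50, n2 = 50, delta = 2, seed = 1) {
  withr::with_seed(seed, list(x1 = rnorm(n1, 0, 1), x2 = rnorm(n2, delta, 1)))
}

# Analytic posterior for N(0,1) vs N(delta,1) with equal priors.
analytic_gaussian_posterior <- function(x, delta) {
  1 / (1 + exp(delta * x - delta^2 / 2))
}

# Independent numeric-integration oracle for the per-node marginal
# likelihood: the Beta-weighted binomial product integrated over the branch
# probability on (0, 1), one factor per group. Never touches lgamma closed
# forms from the package.
oracle_group_integral <- local({
  memo <- new.env(parent = emptyenv())
  function(c0, c1, a) {
    key <- paste(c0, c1, a)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- stats::integrate(
      function(p) p^(c0 + a - 1) * (1 - p)^(c1 + a - 1),
      0, 1, rel.tol = 1e-10)$value /
      stats::integrate(function(p) p^(a - 1) * (1 - p)^(a - 1),
                       0, 1, rel.tol = 1e-10)$value
    memo[[key]] <- val
    val
  }
})

oracle_level_likelihood <- function(l0, l1, m0, m1, n0, n1, a, hypothesis = "H1") {
  if (hypothesis == "H1") {
    oracle_group_integral(l0 + m0, l1 + m1, a) * oracle_group_integral(n0, n1, a)
  } else {
    oracle_group_integral(l0 + n0, l1 + n1, a) * oracle_group_integral(m0, m1, a)
  }
}

# Two planted 2-D Gaussian blobs; sep is the distance between blob centres.
planted_blobs <- function(n_per_class = 20, sep = 3, seed = 1) {
  withr::with_seed(seed, {
    f <- rbind(matrix(rnorm(2 * n_per_class), ncol = 2),
               matrix(rnorm(2 * n_per_class, mean = 0), ncol = 2) +
                 matrix(c(sep, 0), n_per_class, 2, byrow = TRUE))
    list(features = f, labels = rep(c(1, 0), each = n_per_class))
  })
}

sample_skewness <- function(x) {
  z <- (x - mean(x)) / stats::sd(x)
  mean(z^3)
}
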