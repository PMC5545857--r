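cts <- function(l0 = 0, l1 = 0, m0 = 0, m1 = 0, n0 = 0, n1 = 0) {
  list(l0 = l0, l1 = l1, m0 = m0, m1 = m1, n0 = n0, n1 = n1)
}

test_that("per-node marginal likelihood matches hand-computable cases", {
  # a lone point falls left or right with probability 1/2 under alpha = 1
  expect_equal(level_log_likelihood(cts(l0 = 1), alpha = 1), log(1 / 2))
  # no data: likelihood 1 under either hypothesis, any alpha
  for (a in c(0.5, 1, 4, 9)) {
    expect_equal(level_log_likelihood(cts(), a, "H1"), 0)
    expect_equal(level_log_likelihood(cts(), a, "H2"), 0)
  }
  expect_equal(level_log_likelihood(cts(l0 = 1, m0 = 3, m1 = 1, n0 = 1, n1 = 3), 1),
               log(1 / 600))
})

test_that("closed form agrees with the numeric-integration oracle", {
  expect_equal(exp(level_log_likelihood(cts(l0 = 1, m0 = 3, m1 = 1, n0 = 1, n1 = 3), 1)),
               oracle_level_likelihood(1, 0, 3, 1, 1, 3, 1),
               tolerance = 1e-6)
  # random spot-check across both hypotheses (the exhaustive sweep is a
  # separate acceptance property)
  cfg <- withr::with_seed(11, matrix(sample(0:5, 50 * 6, replace = TRUE), ncol = 6))
  for (i in seq_len(nrow(cfg))) {
    v <- cfg[i, ]
    for (hyp in c("H1", "H2")) {
      got <- exp(level_log_likelihood(
        cts(v[1], v[2], v[3], v[4], v[5], v[6]), alpha = 4, hyp))
      want <- oracle_level_likelihood(v[1], v[2], v[3], v[4], v[5], v[6], 4, hyp)
      expect_equal(got, want, tolerance = 1e-6)
    }
  }
})

test_that("H2 exchanges the roles of the two training samples", {
  a <- level_log_likelihood(cts(1, 0, 2, 5, 4, 1), 2, "H2")
  b <- level_log_likelihood(cts(1, 0, 4, 1, 2, 5), 2, "H1")
  expect_identical(a, b)
})

test_that("invalid counts and concentrations are rejected", {
  expect_error(level_log_likelihood(cts(l0 = -1), 1), "non-negative")
  expect_error(level_log_likelihood(cts(), 0), "alpha")
  expect_error(level_log_likelihood(cts(), -2), "alpha")
})

test_that("tree marginal likelihood is symmetric when the samples coincide", {
  x <- withr::with_seed(3, rnorm(40))
  tree <- build_partition(c(x, x), test_points = 0.5)
  expect_identical(log_marginal(tree, 0.5, x, x, "H1"),
                   log_marginal(tree, 0.5, x, x, "H2"))
})

test_that("a single-level tree reproduces the root split term", {
  draws <- gaussian_samples(10, 10, delta = 1, seed = 5)
  tree <- build_partition(c(draws$x1, draws$x2), test_points = 0.2, max_level = 1)
  root <- count_node(tree, "", 0.2, draws$x1, draws$x2)
  for (hyp in c("H1", "H2")) {
    expect_equal(log_marginal(tree, 0.2, draws$x1, draws$x2, hyp),
                 level_log_likelihood(root, alpha = 1, hyp))
  }
})

test_that("the stopping rule makes deeper level caps redundant", {
  for (seed in 1:10) {
    draws <- gaussian_samples(30, 30, delta = 1.5, seed = seed)
    pool <- c(draws$x1, draws$x2)
    t18 <- build_partition(pool, test_points = 0.8, max_level = 18)
    t25 <- build_partition(pool, test_points = 0.8, max_level = 25)
    for (hyp in c("H1", "H2")) {
      expect_equal(log_marginal(t18, 0.8, draws$x1, draws$x2, hyp),
                   log_marginal(t25, 0.8, draws$x1, draws$x2, hyp),
                   tolerance = 1e-10)
    }
  }
})

test_that("points outside the partition space are rejected", {
  tree <- build_partition(c(0, 1, 2))
  expect_error(log_marginal(tree, 99, c(0, 1), c(1, 2)),
               "score outside partition space")
})
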