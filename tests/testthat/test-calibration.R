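test_that("model stores class-size priors unless overridden", {
  draws <- gaussian_samples(161, 153, delta = 2, seed = 2)
  m <- pt_calibrate(draws$x1, draws$x2)
  expect_equal(m$prior_h1, 161 / 314)
  m50 <- pt_calibrate(rnorm(50), rnorm(50))
  expect_equal(m50$prior_h1, 0.5)
  m3 <- pt_calibrate(draws$x1, draws$x2, prior_h1 = 0.3)
  expect_equal(m3$prior_h1, 0.3)
  expect_error(pt_calibrate(numeric(0), draws$x2), "no training scores")
})

test_that("prediction preserves order and matches the per-score posterior", {
  draws <- gaussian_samples(40, 40, delta = 2, seed = 6)
  m <- pt_calibrate(draws$x1, draws$x2)
  scores <- withr::with_seed(8, rnorm(100, 1))
  pred <- predict(m, scores)
  expect_equal(nrow(pred), 100)
  expect_equal(pred$score, scores)
  for (i in c(1, 37, 100)) {
    expect_equal(pred$posterior_h1[i],
                 polya_posterior(scores[i], draws$x1, draws$x2)$posterior_h1)
  }
  expect_error(predict(m, c(1, NA)), "non-finite")
})

test_that("identical class distributions calibrate every score to the prior", {
  x <- withr::with_seed(10, rnorm(30))
  m <- pt_calibrate(x, x)
  pred <- predict(m, c(-1, 0, 1))
  expect_equal(pred$posterior_h1, rep(0.5, 3))
})

test_that("a score at the centre of the positive class calibrates above 1/2", {
  draws <- gaussian_samples(50, 50, delta = 3, seed = 12)
  m <- pt_calibrate(draws$x1, draws$x2)
  expect_gt(predict(m, median(draws$x1))$posterior_h1, 0.5)
})

test_that("leave-one-out scoring holds each subject out exactly once", {
  blobs <- planted_blobs(2, sep = 4, seed = 1)
  calls <- new.env(); calls$n <- 0
  scorer <- list(
    train = function(features, labels) {
      calls$n <- calls$n + 1
      expect_equal(nrow(features), 3)
      kmeans_discriminant(features, labels, seed = 0)
    },
    score = function(model, newdata) predict(model, newdata))
  cv <- cv_scores(blobs$features, blobs$labels, scorer, scheme = "loo")
  expect_equal(calls$n, 4)
  expect_equal(length(cv$x1) + length(cv$x2), 4)
})

test_that("fold assignment is deterministic and leakage-free", {
  blobs <- planted_blobs(50, sep = 2, seed = 3)
  a <- cv_scores(blobs$features, blobs$labels, kmeans_scorer(),
                 scheme = "kfold", k = 10, seed = 5)
  b <- cv_scores(blobs$features, blobs$labels, kmeans_scorer(),
                 scheme = "kfold", k = 10, seed = 5)
  expect_identical(as.numeric(a$x1), as.numeric(b$x1))
  expect_identical(as.numeric(a$x2), as.numeric(b$x2))

  # permuting subject order changes fold membership only: under LOO each
  # subject is scored by a model trained on the same complement
  perm <- withr::with_seed(13, sample(nrow(blobs$features)))
  loo1 <- cv_scores(blobs$features, blobs$labels, kmeans_scorer(), "loo")
  loo2 <- cv_scores(blobs$features[perm, ], blobs$labels[perm],
                    kmeans_scorer(), "loo")
  expect_equal(sort(as.numeric(loo1$x1)), sort(as.numeric(loo2$x1)))
  expect_equal(sort(as.numeric(loo1$x2)), sort(as.numeric(loo2$x2)))
})

test_that("cross-validated k-means scores separate well-separated blobs", {
  blobs <- planted_blobs(30, sep = 5, seed = 21)
  cv <- cv_scores(blobs$features, blobs$labels, kmeans_scorer(),
                  scheme = "kfold", k = 10, seed = 2)
  # low distance-ratio scores favour class 1
  wt <- wilcox.test(as.numeric(cv$x1), as.numeric(cv$x2),
                    alternative = "less")
  expect_lt(wt$p.value, 0.01)
})

test_that("cv input contracts are enforced", {
  blobs <- planted_blobs(5, sep = 3, seed = 2)
  expect_error(cv_scores(blobs$features, rep(1, 10), kmeans_scorer()),
               "2 subjects per class")
  expect_error(cv_scores(blobs$features, blobs$labels, list(train = identity)),
               "scorer")
  expect_error(cv_scores(blobs$features, blobs$labels[-1], kmeans_scorer()),
               "disagree")
})

test_that("self-calibrated training scores trend along the diagonal", {
  draws <- gaussian_samples(500, 500, delta = 2.5, seed = 30)
  m <- pt_calibrate(draws$x1, draws$x2)
  pred <- predict(m, c(draws$x1, draws$x2))
  rd <- reliability_diagram(pred$posterior_h1, rep(c(1, 0), each = 500))
  # bins below ~20 members are dominated by binomial noise (SE > 0.11), so
  # judge the weak monotone trend on the well-populated bins
  big <- rd$bins[rd$bins$count >= 20, ]
  expect_gt(cor(big$mean_predicted, big$frac_positive, method = "spearman"),
            0.9)
})
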