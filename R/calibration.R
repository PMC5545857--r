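#' Fit a Polya-tree calibration model
#'
#' Packages the two class-conditional score distributions, the class prior
#' and the tree depth into a calibration model. The model *is* the data: the
#' nonparametric posterior needs only the raw held-out scores, so fitting
#' amounts to validating and storing them.
#'
#' @param x1 scores of the positive class (class 1), numeric or
#'   [score_sample]; typically held-out cross-validation scores.
#' @param x2 scores of the negative class (class 2).
#' @param prior_h1 prior probability of class 1, or `"from-class-sizes"`
#'   (default): `|x1| / (|x1| + |x2|)`. A user-supplied prior overrides the
#'   class-size default, e.g. to encode a known population prevalence.
#' @param max_level deepest split level of the Polya tree (default 18).
#' @param provenance optional list recording how the scores were produced
#'   (e.g. the cross-validation scheme and seed); stored verbatim.
#' @return an object of class `"pt_calibration"`.
#' @seealso [predict.pt_calibration()], [cv_scores()]
#' @examples
#' set.seed(1)
#' m <- pt_calibrate(rnorm(50), rnorm(50, 2))
#' predict(m, c(-1, 1, 3))
#' @export
pt_calibrate <- function(x1, x2, prior_h1 = "from-class-sizes",
                         max_level = 18, provenance = NULL) {
  x1 <- as_scores(x1, "x1"); x2 <- as_scores(x2, "x2")
  if (identical(prior_h1, "from-class-sizes")) {
    prior_h1 <- length(x1) / (length(x1) + length(x2))
  }
  prior_h1 <- as.numeric(prior_h1)
  if (!is.finite(prior_h1) || prior_h1 <= 0 || prior_h1 >= 1) {
    stop("prior_h1 must lie strictly between 0 and 1")
  }
  max_level <- as.integer(max_level)
  if (is.na(max_level) || max_level < 1L) stop("max_level must be >= 1")
  structure(list(x1 = x1, x2 = x2, prior_h1 = prior_h1,
                 max_level = max_level, provenance = provenance),
            class = "pt_calibration")
}

#' @export
print.pt_calibration <- function(x, ...) {
  cat(sprintf(paste0("Polya-tree calibration model\n",
                     "  class 1: %d scores, class 2: %d scores\n",
                     "  prior Pr(H1) = %.4f, max level %d\n"),
              length(x$x1), length(x$x2), x$prior_h1, x$max_level))
  if (!is.null(x$provenance$scheme)) {
    cat(sprintf("  scores from %s cross-validation\n", x$provenance$scheme))
  }
  invisible(x)
}

#' Calibrate test scores to class-membership probabilities
#'
#' Applies the Polya-tree posterior to each test score in turn. Output rows
#' are in the same order as the input scores.
#'
#' @param object a [pt_calibrate()] model.
#' @param scores numeric vector of test scores to calibrate.
#' @param ... unused.
#' @return a data frame with columns `score`, `posterior_h1`, `log_lik_h1`,
#'   `log_lik_h2`.
#' @export
predict.pt_calibration <- function(object, scores, ...) {
  scores <- as.numeric(scores)
  if (length(scores) == 0L) stop("no test scores")
  if (!all(is.finite(scores))) stop("non-finite score in test scores")
  res <- vapply(scores, function(s) {
    p <- polya_posterior(s, object$x1, object$x2,
                         prior_h1 = object$prior_h1,
                         max_level = object$max_level)
    c(p$posterior_h1, p$log_lik_h1, p$log_lik_h2)
  }, numeric(3))
  data.frame(score = scores,
             posterior_h1 = res[1, ],
             log_lik_h1 = res[2, ],
             log_lik_h2 = res[3, ])
}

#' Held-out classifier scores via cross-validation
#'
#' Generates the class-conditional score distributions that a calibration
#' model is built from. Every subject is scored by a model trained without
#' that subject's fold, so the returned distributions reflect out-of-sample
#' behaviour of the scorer. Folds in the k-fold scheme are stratified by
#' class (so no training fold can lose a class by chance) and the assignment
#' is deterministic given `seed`.
#'
#' @param features data frame or matrix of numeric features, one row per
#'   subject.
#' @param labels binary vector (`1` = positive/class 1, `0` = negative), one
#'   per row of `features`.
#' @param scorer a scorer contract: a list with elements
#'   `train(features, labels)` returning a fitted model, and
#'   `score(model, newdata)` returning one real score per row of `newdata`.
#'   See [kmeans_scorer()] for the built-in example.
#' @param scheme `"loo"` (leave-one-out, default) or `"kfold"`.
#' @param k number of folds when `scheme = "kfold"` (default 10).
#' @param seed integer seed controlling fold assignment.
#' @return a list with `x1`, `x2` ([score_sample]s of held-out scores split
#'   by true label), `scheme`, `k`, and `seed`.
#' @examples
#' set.seed(3)
#' feats <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 3), ncol = 2))
#' labs <- rep(c(1, 0), each = 20)
#' cv <- cv_scores(feats, labs, kmeans_scorer(), scheme = "kfold", k = 5, seed = 1)
#' length(cv$x1)
#' @export
cv_scores <- function(features, labels, scorer, scheme = c("loo", "kfold"),
                      k = 10, seed = 0) {
  scheme <- match.arg(scheme)
  features <- as.matrix(features)
  labels <- as.numeric(labels)
  if (nrow(features) != length(labels)) {
    stop("features and labels disagree in length")
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  if (sum(labels == 1) < 2 || sum(labels == 0) < 2) {
    stop("need at least 2 subjects per class")
  }
  if (!is.list(scorer) || !is.function(scorer$train) || !is.function(scorer$score)) {
    stop("scorer must be a list with train() and score() functions")
  }
  n <- nrow(features)

  fold <- integer(n)
  if (scheme == "loo") {
    fold <- seq_len(n)
    k <- n
  } else {
    k <- as.integer(k)
    if (is.na(k) || k < 2L || k > n) stop("k must be between 2 and n")
    # stratified: shuffle within each class, deal round-robin into k folds
    withr::with_seed(seed, {
      for (cls in c(1, 0)) {
        idx <- sample(which(labels == cls))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    })
  }

  scores <- numeric(n)
  for (f in sort(unique(fold))) {
    hold <- fold == f
    train_labs <- labels[!hold]
    if (length(unique(train_labs)) < 2L) stop("degenerate fold: a training fold contains a single class")
    model <- scorer$train(features[!hold, , drop = FALSE], train_labs)
    scores[hold] <- scorer$score(model, features[hold, , drop = FALSE])
  }
  if (!all(is.finite(scores))) stop("scorer returned non-finite scores")

  list(x1 = score_sample(scores[labels == 1], 1),
       x2 = score_sample(scores[labels == 0], 2),
       scheme = scheme, k = k, seed = seed)
}
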