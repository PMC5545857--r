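#' k-means distance-ratio discriminant
#'
#' A deliberately marginal scorer: the feature table is clustered with
#' k-means (k = 2, standard Lloyd iterations, seeded), each cluster is
#' labelled by the majority true class of its members, and the score of a
#' point is the ratio of its Euclidean distances to the class-1 and class-2
#' centroids. Low scores favour class 1. The score distributions this
#' produces are strongly non-Gaussian and overlapping, which is exactly what
#' makes it a useful stress test for a calibration method.
#'
#' Label assignment: each cluster takes the majority class of its members,
#' ties broken toward class 1; if both clusters end up with the same majority
#' label, the cluster with the higher class-1 fraction becomes the class-1
#' centroid.
#'
#' @param features numeric matrix or data frame, one row per subject.
#' @param labels binary vector (`1` = class 1/positive, `0` = class 2).
#' @param seed integer seed for the k-means initialisation.
#' @return an object of class `"kmeans_discriminant"` with fields
#'   `centroid_1`, `centroid_2` (feature-space vectors).
#' @examples
#' set.seed(2)
#' feats <- rbind(matrix(rnorm(20), ncol = 2), matrix(rnorm(20, 4), ncol = 2))
#' labs <- rep(c(1, 0), each = 10)
#' disc <- kmeans_discriminant(feats, labs)
#' predict(disc, feats[1:3, ])
#' @export
kmeans_discriminant <- function(features, labels, seed = 0) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.numeric(labels)
  if (nrow(features) < 2L) stop("need at least 2 subjects")
  if (nrow(features) != length(labels)) stop("features and labels disagree in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  if (all(apply(features, 2, function(col) max(col) == min(col)))) {
    stop("degenerate clustering: all points identical")
  }
  km <- withr::with_seed(seed, stats::kmeans(features, centers = 2, nstart = 10))
  frac1 <- vapply(1:2, function(cl) mean(labels[km$cluster == cl] == 1), 0)
  c1 <- which.max(frac1)          # ties resolve to the first cluster
  structure(list(centroid_1 = km$centers[c1, ],
                 centroid_2 = km$centers[3L - c1, ]),
            class = "kmeans_discriminant")
}

#' @export
print.kmeans_discriminant <- function(x, ...) {
  cat(sprintf("k-means discriminant in %d dimensions\n", length(x$centroid_1)))
  cat("  class-1 centroid:", format(x$centroid_1, digits = 4), "\n")
  cat("  class-2 centroid:", format(x$centroid_2, digits = 4), "\n")
  invisible(x)
}

#' Score new points with a k-means discriminant
#'
#' Returns `d(x, centroid_1) / d(x, centroid_2)` (Euclidean distances) for
#' each row of `newdata`; lower scores favour class 1. A point coinciding
#' with the class-2 centroid would divide by zero and is capped at the
#' sentinel `1e6`.
#'
#' @param object a [kmeans_discriminant()] model.
#' @param newdata numeric vector (a single point) or matrix of points.
#' @param ... unused.
#' @return numeric vector of distance-ratio scores.
#' @export
predict.kmeans_discriminant <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$centroid_1)) {
    stop("dimension mismatch: model has ", length(object$centroid_1),
         " features, data has ", ncol(newdata))
  }
  d1 <- sqrt(rowSums(sweep(newdata, 2, object$centroid_1)^2))
  d2 <- sqrt(rowSums(sweep(newdata, 2, object$centroid_2)^2))
  ifelse(d2 == 0, 1e6, pmin(d1 / d2, 1e6))
}

#' Scorer contract wrapping the k-means discriminant
#'
#' Adapts [kmeans_discriminant()] to the `train`/`score` contract expected
#' by [cv_scores()].
#'
#' @param seed seed passed to every [kmeans_discriminant()] fit.
#' @return a list with `train(features, labels)` and `score(model, newdata)`.
#' @export
kmeans_scorer <- function(seed = 0) {
  list(train = function(features, labels) kmeans_discriminant(features, labels, seed = seed),
       score = function(model, newdata) predict(model, newdata))
}
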