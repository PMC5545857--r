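#' Labelled sample of classifier scores
#'
#' A `score_sample` holds the real-valued classifier scores observed for one
#' class of a binary problem, typically collected on held-out folds during
#' cross-validation. Scores are stored sorted in ascending order; sorting is
#' canonical so that two samples with the same values compare equal.
#'
#' @param scores numeric vector of classifier scores; must be non-empty and
#'   finite. Score units are whatever the classifier emits (dimensionless).
#' @param class_label which class the sample belongs to, `1` (positive) or
#'   `2` (negative).
#' @return a numeric vector of class `"score_sample"`, sorted ascending, with
#'   a `class_label` attribute.
#' @examples
#' x1 <- score_sample(c(0.3, -1.2, 0.8), class_label = 1)
#' x1
#' @export
score_sample <- function(scores, class_label = 1) {
  scores <- as.numeric(scores)
  if (length(scores) == 0L) {
    stop("no training scores: a score sample must be non-empty")
  }
  if (!all(is.finite(scores))) {
    stop("non-finite score in sample")
  }
  if (!class_label %in% c(1, 2)) {
    stop("class_label must be 1 or 2")
  }
  structure(sort(scores), class = "score_sample",
            class_label = as.integer(class_label))
}

#' @export
print.score_sample <- function(x, ...) {
  cat(sprintf("score_sample: %d scores, class %d, range [%g, %g]\n",
              length(x), attr(x, "class_label"), min(x), max(x)))
  invisible(x)
}

# Coerce a numeric vector or score_sample to a plain sorted numeric vector.
as_scores <- function(x, what = "scores") {
  if (length(x) == 0L) stop("no training scores: ", what, " is empty")
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("non-finite score in ", what)
  sort(x)
}
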