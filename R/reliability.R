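#' Reliability diagram with diagonal goodness-of-fit
#'
#' Sorts predicted probabilities into 10 fixed-width bins over `[0, 1]`
#' (`[0, 0.1), ..., [0.9, 1]`; a prediction of exactly 1 falls in the top
#' bin) and summarises each occupied bin by its mean predicted probability,
#' the empirical fraction of positives, the member count and the spread of
#' the predictions. Perfect calibration puts every bin on the diagonal
#' `frac_positive = mean_predicted`; the weighted chi-squared fit to that
#' diagonal, the number of occupied bins (granularity) and the spread of the
#' mean predictions (range) are attached as summary metrics.
#'
#' @param posterior numeric vector of predicted class-1 probabilities in
#'   `[0, 1]`.
#' @param labels binary vector of true labels (`1` = positive), same length.
#' @return an object of class `"reliability_diagram"`: a list with `bins`
#'   (data frame: `bin`, `mean_predicted`, `frac_positive`, `count`,
#'   `sd_predicted`), `chi2`, `dof`, `p_value`, `n_calibrated_points`,
#'   `range`, `n`.
#' @seealso [chi2_diagonal_fit()]
#' @examples
#' rd <- reliability_diagram(c(0.05, 0.05, 0.95, 0.95), c(0, 0, 1, 1))
#' rd$bins
#' rd$range
#' @export
reliability_diagram <- function(posterior, labels) {
  posterior <- as.numeric(posterior)
  labels <- as.numeric(labels)
  if (length(posterior) == 0L) stop("no predictions")
  if (length(posterior) != length(labels)) {
    stop("predictions and labels disagree in length")
  }
  if (any(!is.finite(posterior)) || any(posterior < 0 | posterior > 1)) {
    stop("predicted probabilities must lie in [0, 1]")
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")

  bin <- pmin(floor(posterior * 10) + 1L, 10L)
  occ <- sort(unique(bin))
  bins <- data.frame(
    bin = occ,
    mean_predicted = vapply(occ, function(b) mean(posterior[bin == b]), 0),
    frac_positive = vapply(occ, function(b) mean(labels[bin == b]), 0),
    count = vapply(occ, function(b) sum(bin == b), 0L),
    sd_predicted = vapply(occ, function(b) {
      s <- stats::sd(posterior[bin == b]); if (is.na(s)) 0 else s
    }, 0)
  )
  out <- structure(list(bins = bins,
                        n_calibrated_points = nrow(bins),
                        range = if (nrow(bins) > 1)
                          max(bins$mean_predicted) - min(bins$mean_predicted)
                        else 0,
                        n = length(posterior)),
                   class = "reliability_diagram")
  fit <- chi2_diagonal_fit(out)
  out$chi2 <- fit$chi2
  out$dof <- fit$dof
  out$p_value <- fit$p_value
  out
}

#' Weighted chi-squared fit of a reliability diagram to the diagonal
#'
#' Quantifies the goodness of fit to a slope of 1 by weighting each occupied
#' bin's residual `frac_positive - mean_predicted` by the inverse of the
#' standard deviation of the calibrated probability in that bin: the binomial
#' standard error the bin's mean calibrated probability implies for its
#' observed positive fraction, `sqrt(m (1 - m) / count)`. A bin whose mean
#' prediction is exactly 0 or 1 would get zero weight; its standard error is
#' floored at `1/(2 count)`, the half-width resolution of a count-based
#' frequency. The degrees of freedom equal the number of occupied bins (the
#' diagonal is fixed, no parameter is estimated) and the p-value is the
#' upper tail of the corresponding chi-squared distribution.
#'
#' @param diagram a [reliability_diagram()] object.
#' @return a list with `chi2`, `dof`, `p_value`.
#' @export
chi2_diagonal_fit <- function(diagram) {
  if (!inherits(diagram, "reliability_diagram")) stop("not a reliability_diagram")
  b <- diagram$bins
  if (nrow(b) == 0L) stop("no occupied bins")
  se <- sqrt(b$mean_predicted * (1 - b$mean_predicted) / b$count)
  floor_se <- 1 / (2 * b$count)
  se <- pmax(se, floor_se)
  chi2 <- sum(((b$frac_positive - b$mean_predicted) / se)^2)
  dof <- nrow(b)
  list(chi2 = chi2, dof = dof,
       p_value = stats::pchisq(chi2, df = dof, lower.tail = FALSE))
}

#' @export
print.reliability_diagram <- function(x, ...) {
  cat(sprintf("Reliability diagram: %d predictions in %d occupied bins\n",
              x$n, x$n_calibrated_points))
  print(x$bins, row.names = FALSE, digits = 4)
  cat(sprintf("chi2 = %.3f on %d dof, p = %.4f; range = %.3f\n",
              x$chi2, x$dof, x$p_value, x$range))
  invisible(x)
}

#' @param x a `reliability_diagram`.
#' @param ... passed to [graphics::plot()].
#' @rdname reliability_diagram
#' @export
plot.reliability_diagram <- function(x, ...) {
  graphics::plot(x$bins$mean_predicted, x$bins$frac_positive,
                 xlim = c(0, 1), ylim = c(0, 1), pch = 19,
                 xlab = "Mean predicted probability",
                 ylab = "Fraction of positives", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
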