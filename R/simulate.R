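#' Convert between Gaussian overlap and mean separation
#'
#' The simulated experiment parameterises class separation by the overlap
#' coefficient of two unit-variance Gaussians: the shared area under their
#' densities, `overlap = 2 * pnorm(-delta / 2)` for mean separation `delta`.
#' `overlap = 1` corresponds to identical distributions (`delta = 0`).
#'
#' @param overlap overlap coefficient in `(0, 1]`.
#' @param delta non-negative mean separation (score units).
#' @return `overlap_to_delta()` returns the separation; `delta_to_overlap()`
#'   the overlap coefficient.
#' @examples
#' overlap_to_delta(2 * pnorm(-1))  # = 2
#' @export
overlap_to_delta <- function(overlap) {
  if (any(!is.finite(overlap)) || any(overlap <= 0 | overlap > 1)) {
    stop("overlap must lie in (0, 1]")
  }
  -2 * stats::qnorm(overlap / 2)
}

#' @rdname overlap_to_delta
#' @export
delta_to_overlap <- function(delta) {
  if (any(!is.finite(delta)) || any(delta < 0)) stop("delta must be >= 0")
  2 * stats::pnorm(-delta / 2)
}

#' Simulate classifier scores for two classes with controlled overlap
#'
#' Draws positive-class scores from N(0, 1) and negative-class scores from
#' N(delta, 1), where `delta` is fixed by the requested overlap coefficient.
#' This emulates a classifier whose score distributions for the two classes
#' are Gaussian with a known degree of confusion.
#'
#' @param overlap overlap coefficient in `(0, 1]`.
#' @param n_pos,n_neg sample sizes per class (default 50 each, the training
#'   size of the simulated experiment).
#' @param seed integer seed.
#' @return a list with `x1`, `x2` ([score_sample]s), `overlap`, `delta`.
#' @examples
#' s <- simulate_scores(0.5, seed = 1)
#' s$delta
#' @export
simulate_scores <- function(overlap, n_pos = 50, n_neg = 50, seed = 0) {
  delta <- overlap_to_delta(overlap)
  if (n_pos < 1 || n_neg < 1) stop("need at least one score per class")
  draws <- withr::with_seed(seed, list(pos = stats::rnorm(n_pos, 0, 1),
                                       neg = stats::rnorm(n_neg, delta, 1)))
  list(x1 = score_sample(draws$pos, 1), x2 = score_sample(draws$neg, 2),
       overlap = overlap, delta = delta)
}

#' Overlap-sweep experiment on simulated Gaussian scores
#'
#' For each overlap level: draw 50 + 50 training scores (per
#' `n_train_per_class`), fit a Polya-tree calibration with class-size priors,
#' draw a balanced test set of `n_test` scores, calibrate them, and build a
#' 10-bin reliability diagram. This is repeated `n_reps` times per overlap
#' and the chi-squared p-value, number of calibrated points (occupied bins)
#' and range of calibrated probabilities are averaged over repetitions.
#'
#' @param overlaps vector of overlap coefficients in `(0, 1]`; the default
#'   grid spans 0.1 to 0.9.
#' @param n_train_per_class training scores per class (default 50).
#' @param n_test total test scores, balanced between classes; must be even
#'   (default 100).
#' @param n_reps repetitions per overlap level (default 20).
#' @param seed integer seed; all randomness in the sweep derives from it.
#' @param max_level Polya-tree depth (default 18).
#' @return an object of class `"pt_sweep"`: a data frame with columns
#'   `overlap`, `mean_p_value`, `mean_n_points`, `mean_range`, and
#'   attributes `n_reps` and `seed`.
#' @examples
#' \donttest{
#' sw <- run_overlap_sweep(c(0.3, 0.9), n_reps = 3, seed = 1)
#' sw
#' }
#' @export
run_overlap_sweep <- function(overlaps = seq(0.1, 0.9, by = 0.1),
                              n_train_per_class = 50, n_test = 100,
                              n_reps = 20, seed = 0, max_level = 18) {
  if (any(!is.finite(overlaps)) || any(overlaps <= 0 | overlaps > 1)) {
    stop("overlap must lie in (0, 1]")
  }
  if (n_test %% 2 != 0) stop("n_test must be even (balanced test set)")
  if (n_reps < 1) stop("n_reps must be >= 1")
  # one sub-seed per (overlap, rep, train/test) draw, all derived from `seed`
  sub_seeds <- withr::with_seed(seed, array(
    sample.int(.Machine$integer.max, length(overlaps) * n_reps * 2),
    dim = c(length(overlaps), n_reps, 2)))

  rows <- lapply(seq_along(overlaps), function(i) {
    stats_rep <- vapply(seq_len(n_reps), function(r) {
      train <- simulate_scores(overlaps[i], n_train_per_class,
                               n_train_per_class, seed = sub_seeds[i, r, 1])
      test <- simulate_scores(overlaps[i], n_test / 2, n_test / 2,
                              seed = sub_seeds[i, r, 2])
      model <- pt_calibrate(train$x1, train$x2, max_level = max_level)
      pred <- predict(model, c(as.numeric(test$x1), as.numeric(test$x2)))
      labels <- rep(c(1, 0), c(n_test / 2, n_test / 2))
      rd <- reliability_diagram(pred$posterior_h1, labels)
      c(rd$p_value, rd$n_calibrated_points, rd$range)
    }, numeric(3))
    data.frame(overlap = overlaps[i],
               mean_p_value = mean(stats_rep[1, ]),
               mean_n_points = mean(stats_rep[2, ]),
               mean_range = mean(stats_rep[3, ]))
  })
  structure(do.call(rbind, rows), n_reps = n_reps, seed = seed,
            class = c("pt_sweep", "data.frame"))
}

#' @param x a `pt_sweep` result.
#' @param ... unused.
#' @rdname run_overlap_sweep
#' @export
plot.pt_sweep <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$overlap, x$mean_p_value, type = "b", pch = 19, col = "red",
                 xlab = "Overlap", ylab = expression(chi^2 ~ "p-value"))
  graphics::plot(x$overlap, x$mean_n_points, type = "b", pch = 19, col = "red",
                 xlab = "Overlap", ylab = "Calibrated points", ylim = c(0, 10))
  graphics::plot(x$overlap, x$mean_range, type = "b", pch = 19, col = "red",
                 xlab = "Overlap", ylab = "Range", ylim = c(0, 1))
  invisible(x)
}
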