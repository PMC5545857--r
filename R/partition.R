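#' Build the dyadic partition space over the score axis
#'
#' Constructs the nested binary partition on which the Polya-tree marginal
#' likelihoods are evaluated. The interval is centred at the median of the
#' pooled training scores and expanded symmetrically until it contains every
#' training score and every test score supplied, with a tiny relative padding
#' so the maximum falls strictly inside the half-open interval
#' `[lower, upper)`. Nodes are indexed by binary strings: the root `""` spans
#' the whole interval, `"0"`/`"1"` its halves, and so on; the bin of string
#' `s` at level `L = nchar(s)` is `[lower + k*w, lower + (k+1)*w)` with
#' `w = (upper - lower)/2^L` and `k` the integer value of `s` read as binary.
#'
#' The Beta concentration at level `L` is `alpha(L) = L^2`, which makes deep,
#' data-poor splits increasingly uninformative and yields absolutely
#' continuous realisations of the process.
#'
#' @param train pooled training scores (numeric vector or [score_sample];
#'   both classes together).
#' @param test_points scores that must also fall inside the partition space
#'   (default none).
#' @param max_level deepest split level evaluated (default 18).
#' @return an object of class `"pt_partition"`: a list with elements `lower`,
#'   `upper`, `center`, `half_width`, `max_level`.
#' @examples
#' tree <- build_partition(c(0, 1, 2, 3))
#' tree
#' @export
build_partition <- function(train, test_points = numeric(0), max_level = 18) {
  train <- as_scores(train, "training pool")
  if (length(test_points)) {
    test_points <- as.numeric(test_points)
    if (!all(is.finite(test_points))) stop("non-finite score in test points")
  }
  max_level <- as.integer(max_level)
  if (is.na(max_level) || max_level < 1L) stop("max_level must be >= 1")

  center <- stats::median(train)
  pts <- c(train, test_points)
  spread <- max(center - min(pts), max(pts) - center)
  # relative padding keeps max(pts) strictly below upper; absolute floor keeps
  # the interval non-degenerate when every point coincides
  half_width <- max(spread * (1 + 1e-9), 1e-6)
  lower <- center - half_width
  upper <- center + half_width
  if (!(lower < upper) || any(pts < lower) || any(pts >= upper)) {
    # pathological magnitudes (e.g. center ~ 1e18 with tiny spread): widen
    # until the floating-point interval genuinely contains the points
    while (!(lower < upper) || any(pts < lower) || any(pts >= upper)) {
      half_width <- half_width * 2
      lower <- center - half_width
      upper <- center + half_width
    }
  }
  structure(list(lower = lower, upper = upper, center = center,
                 half_width = half_width, max_level = max_level),
            class = "pt_partition")
}

#' @export
print.pt_partition <- function(x, ...) {
  cat(sprintf("Polya-tree partition space [%g, %g), max level %d\n",
              x$lower, x$upper, x$max_level))
  invisible(x)
}

# Bin [a, b) of a node given its binary-string index.
node_bin <- function(tree, node) {
  if (!inherits(tree, "pt_partition")) stop("not a pt_partition")
  if (length(node) != 1L || is.na(node) || grepl("[^01]", node)) {
    stop("node must be a binary string such as \"\", \"0\", \"01\"")
  }
  level <- nchar(node)
  if (level >= tree$max_level) {
    stop("node outside tree: level ", level,
         " cannot be split within max_level ", tree$max_level)
  }
  if (level == 0L) {
    return(c(tree$lower, tree$upper))
  }
  w <- (tree$upper - tree$lower) / 2^level
  k <- strtoi(node, base = 2L)
  c(tree$lower + k * w, tree$lower + (k + 1) * w)
}

#' Count the three samples into a node's left and right halves
#'
#' Splits a node's bin at its midpoint and counts, for the test point `xp`
#' and the two class samples, how many values fall on each side. Bins are
#' half-open `[a, mid)` and `[mid, b)`: a value exactly at the midpoint goes
#' right, which makes the counting deterministic.
#'
#' @param tree a [build_partition()] object.
#' @param node binary-string node index (`""` is the root).
#' @param xp the test score (length-1 numeric), or `numeric(0)` for none.
#' @param x1,x2 class-1 and class-2 score samples (numeric or
#'   [score_sample]).
#' @return a list of class `"count_triple"` with fields `node`, `l0`, `l1`
#'   (test-point counts), `m0`, `m1` (class 1), `n0`, `n1` (class 2).
#' @examples
#' tree <- build_partition(c(0.5, 1, 3, 3.5))
#' count_node(tree, "", xp = 3.2, x1 = c(0.5, 1), x2 = c(3, 3.5))
#' @export
count_node <- function(tree, node, xp, x1, x2) {
  bin <- node_bin(tree, node)
  mid <- (bin[1] + bin[2]) / 2
  # empty samples are legal here: a node only sees what falls in its bin
  x1 <- as.numeric(x1); x2 <- as.numeric(x2); xp <- as.numeric(xp)
  if (!all(is.finite(c(x1, x2, xp)))) stop("non-finite score")
  in_bin <- function(v) v[v >= bin[1] & v < bin[2]]
  x1 <- in_bin(x1); x2 <- in_bin(x2); xp <- in_bin(xp)
  structure(list(node = node,
                 l0 = sum(xp < mid), l1 = sum(xp >= mid),
                 m0 = sum(x1 < mid), m1 = sum(x1 >= mid),
                 n0 = sum(x2 < mid), n1 = sum(x2 >= mid)),
            class = "count_triple")
}
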