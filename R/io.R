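#' Read a labelled score table
#'
#' Reads a CSV with header columns `id`, `score`, `label` (label 1 =
#' positive/class 1, 0 = negative) and splits it into the two class samples.
#' Malformed rows are rejected with the offending row number.
#'
#' @param path path to the CSV file.
#' @return a list with `x1`, `x2` ([score_sample]s) and `ids` (list with the
#'   ids per class, in score-table order).
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("id", "score", "label")
  if (!all(need %in% names(tab))) {
    stop("score table must have header columns id, score, label")
  }
  if (nrow(tab) == 0L) stop("score table is empty")
  score <- suppressWarnings(as.numeric(tab$score))
  bad <- which(!is.finite(score))
  if (length(bad)) {
    stop("malformed score in row ", bad[1], ": \"", tab$score[bad[1]], "\"")
  }
  bad <- which(!tab$label %in% c("0", "1"))
  if (length(bad)) {
    stop("unknown label in row ", bad[1], ": \"", tab$label[bad[1]],
         "\" (expected 0 or 1)")
  }
  lab <- as.integer(tab$label)
  if (!any(lab == 1) || !any(lab == 0)) {
    stop("score table must contain both labels 0 and 1")
  }
  list(x1 = score_sample(score[lab == 1], 1),
       x2 = score_sample(score[lab == 0], 2),
       ids = list(x1 = tab$id[lab == 1], x2 = tab$id[lab == 0]))
}

#' Write a labelled score table
#'
#' Writes the two class samples as a CSV with columns `id`, `score`,
#' `label`. Scores are printed with 17 significant digits so a
#' write-then-read round trip preserves every value bit-exactly.
#'
#' @param x1,x2 class score samples (numeric or [score_sample]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(x1, x2, path) {
  x1 <- as_scores(x1, "x1"); x2 <- as_scores(x2, "x2")
  df <- data.frame(
    id = c(sprintf("pos%03d", seq_along(x1)), sprintf("neg%03d", seq_along(x2))),
    score = sprintf("%.17g", c(x1, x2)),
    label = rep(c(1L, 0L), c(length(x1), length(x2))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize / restore a calibration model as JSON
#'
#' The model is the data: the JSON holds the sorted score arrays, the prior,
#' the tree depth and the provenance record. No binary formats are used.
#'
#' @param model a [pt_calibrate()] object.
#' @param path JSON file path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns the restored `pt_calibration`.
#' @export
write_calibration <- function(model, path) {
  if (!inherits(model, "pt_calibration")) stop("not a pt_calibration model")
  jsonlite::write_json(
    list(x1 = as.numeric(model$x1), x2 = as.numeric(model$x2),
         prior_h1 = model$prior_h1, max_level = model$max_level,
         provenance = model$provenance),
    path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("x1", "x2", "prior_h1", "max_level")
  if (!all(need %in% names(obj))) stop("not a calibration model file: ", path)
  pt_calibrate(obj$x1, obj$x2, prior_h1 = obj$prior_h1,
               max_level = obj$max_level,
               provenance = if (length(obj$provenance)) obj$provenance else NULL)
}

#' Write calibrated predictions as CSV
#'
#' @param predictions a [predict.pt_calibration()] data frame.
#' @param path output CSV path.
#' @param ids optional id column (defaults to row numbers).
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path, ids = NULL) {
  if (is.null(ids)) ids <- seq_len(nrow(predictions))
  df <- cbind(data.frame(id = ids), predictions)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
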