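# Readers and writers for the score CSV, fit JSON, and grid CSV formats.

#' Read a labeled score table from CSV
#'
#' Expects a header with at least the columns `score` and `label`
#' (`sample_id` is optional and generated when absent). Scores must be
#' numeric probabilities in \eqn{[0, 1]}. Label columns that are not already
#' 0/1 are mapped by naming the positive label explicitly.
#'
#' @param path CSV file path (RFC-4180, header required).
#' @param positive Value of `label` to treat as the positive class when the
#'   column is not 0/1 coded.
#' @return A [labeled_scores()] data frame.
#' @export
read_scores <- function(path, positive = NULL) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("score", "label")) {
    if (!col %in% names(df)) {
      stop(sprintf("column `%s` is missing from %s", col, path))
    }
  }
  score <- suppressWarnings(as.numeric(df$score))
  if (anyNA(score)) {
    bad <- which(is.na(score)) + 1L  # +1 for the header line
    stop(sprintf("non-numeric score value(s) on line(s) %s of %s",
                 paste(utils::head(bad, 5L), collapse = ", "), path))
  }
  label <- df$label
  if (!is.null(positive)) {
    vals <- unique(label)
    if (length(vals) > 2L) {
      stop("`label` column has more than two distinct values")
    }
    label <- as.integer(label == positive)
  }
  labeled_scores(score, label,
                 sample_id = if ("sample_id" %in% names(df)) df$sample_id
                             else NULL)
}

#' Write a labeled score table to CSV
#'
#' Lossless at full double precision: [read_scores()] on the output
#' reproduces the table exactly.
#'
#' @param x A [labeled_scores()] data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(x, path) {
  stopifnot(is.data.frame(x), all(c("score", "label") %in% names(x)))
  out <- data.frame(
    sample_id = if ("sample_id" %in% names(x)) x$sample_id
                else seq_len(nrow(x)),
    score = sprintf("%.17g", x$score),
    label = x$label
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize an optimizer result to JSON
#'
#' Canonical machine-readable output: the best point, the interval bounds at
#' full precision, every evaluated grid point as a flat record list, and the
#' Pareto front.
#'
#' @param fit An `abstention_fit` from [fit_symmetric()] or
#'   [fit_asymmetric()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "abstention_fit"))
  payload <- list(
    mode = fit$mode,
    best = as.list(fit$best),
    interval = list(lower = fit$interval$lower, upper = fit$interval$upper,
                    anchor = fit$interval$anchor,
                    half_width = fit$interval$half_width,
                    clipped = fit$interval$clipped),
    grid = fit$grid,
    pareto_front = fit$pareto_front
  )
  jsonlite::write_json(payload, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' Write the evaluated grid as a tidy CSV
#'
#' One row per evaluated `(half_width, anchor)` combination with columns
#' `half_width, anchor, mcc, size_fraction, objective` — ready for heatmap
#' rendering of the objective surface.
#'
#' @inheritParams write_fit_json
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(fit, path) {
  stopifnot(inherits(fit, "abstention_fit"))
  utils::write.csv(fit$grid, path, row.names = FALSE)
  invisible(path)
}
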