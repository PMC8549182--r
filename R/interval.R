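# Abstention intervals and trichotomized classification.

#' Construct an abstention interval
#'
#' The interval of positive-class probability scores on which the classifier
#' abstains. It is parameterized by an `anchor` (the offset of its center
#' from the default decision threshold 0.5) and a `half_width`:
#' \deqn{L = 0.5 + \mathrm{anchor} - \mathrm{half\_width}, \qquad
#'       U = 0.5 + \mathrm{anchor} + \mathrm{half\_width}.}
#' A zero anchor gives a symmetric interval around 0.5; a nonzero anchor
#' shifts it toward one class. Bounds falling outside \eqn{[0, 1]} are
#' clipped, with a warning.
#'
#' @param anchor Offset of the interval center from 0.5 (may be negative).
#' @param half_width Half the interval width; must be \eqn{\ge 0}.
#' @return An object of class `abstention_interval` with fields `anchor`,
#'   `half_width`, `lower`, `upper`, and `clipped` (logical).
#' @examples
#' abstention_interval(anchor = 0, half_width = 0.13)  # [0.37, 0.63]
#' @export
abstention_interval <- function(anchor = 0, half_width = 0) {
  if (!is.numeric(anchor) || length(anchor) != 1L || !is.finite(anchor)) {
    stop("`anchor` must be a single finite number")
  }
  if (!is.numeric(half_width) || length(half_width) != 1L ||
      !is.finite(half_width) || half_width < 0) {
    stop("`half_width` must be a single number >= 0")
  }
  lower <- 0.5 + anchor - half_width
  upper <- 0.5 + anchor + half_width
  clipped <- lower < 0 || upper > 1
  if (clipped) {
    warning(sprintf(
      "abstention interval [%.4f, %.4f] clipped to [0, 1]", lower, upper))
    lower <- max(0, min(1, lower))
    upper <- max(0, min(1, upper))
  }
  structure(
    list(anchor = anchor, half_width = half_width,
         lower = lower, upper = upper, clipped = clipped),
    class = "abstention_interval"
  )
}

#' @export
print.abstention_interval <- function(x, ...) {
  cat(sprintf(
    "Abstention interval [%.3f, %.3f] (anchor = %.4f, half-width = %.3f)%s\n",
    x$lower, x$upper, x$anchor, x$half_width,
    if (x$clipped) " [clipped]" else ""))
  invisible(x)
}

#' Trichotomize probability scores with an abstention interval
#'
#' Scores strictly inside the interval are rejected; scores at or above the
#' upper bound are classified positive, at or below the lower bound negative.
#' Boundary equality therefore classifies rather than rejects, which
#' maximizes coverage. With a zero-width interval at 0.5 this reduces to the
#' plain threshold rule \eqn{p \ge 0.5 \Rightarrow} positive.
#'
#' @param scores Numeric vector of positive-class probabilities in
#'   \eqn{[0, 1]}.
#' @param interval An [abstention_interval()].
#' @return An integer vector the same length as `scores` over `{0, 1, NA}`,
#'   with `NA` marking rejected samples.
#' @examples
#' classify_with_abstention(c(0.1, 0.5, 0.9), abstention_interval(0, 0.13))
#' @export
classify_with_abstention <- function(scores, interval) {
  if (!inherits(interval, "abstention_interval")) {
    stop("`interval` must be an abstention_interval object")
  }
  scores <- validate_scores(scores)
  out <- rep(NA_integer_, length(scores))
  out[scores <= interval$lower] <- 0L
  # assigned last so that a zero-width interval sends p == bound to positive
  out[scores >= interval$upper] <- 1L
  out
}

validate_scores <- function(scores) {
  if (!is.numeric(scores) || length(scores) == 0L) {
    stop("`scores` must be a nonempty numeric vector")
  }
  if (anyNA(scores) || any(scores < 0 | scores > 1)) {
    stop("all scores must lie in [0, 1]")
  }
  as.numeric(scores)
}

#' Evaluate MCC and coverage of one abstention interval
#'
#' The cost function of the grid-search optimizers: builds the interval for
#' `(anchor, half_width)`, trichotomizes the scores, and returns the MCC of
#' the classified samples together with the fraction classified. With
#' `half_width = 0` and `anchor = 0` it reproduces the plain 0.5-threshold
#' classifier at full coverage.
#'
#' @param scores Positive-class probabilities in \eqn{[0, 1]}, or a
#'   [labeled_scores()] data frame (then `labels` may be omitted).
#' @param labels Binary ground-truth labels aligned with `scores`.
#' @param anchor Offset of the interval center from 0.5.
#' @param half_width Half the interval width; must lie in \eqn{[0, 0.5]}
#'   (0.5 on each side already covers the whole probability range).
#' @return A list with elements `mcc` and `size_fraction`.
#' @examples
#' abstention_cost(c(0.2, 0.8, 0.55, 0.45), c(0, 1, 0, 1),
#'                 anchor = 0, half_width = 0.1)
#' @export
abstention_cost <- function(scores, labels = NULL, anchor = 0, half_width = 0) {
  xy <- resolve_scores_labels(scores, labels)
  if (!is.numeric(half_width) || length(half_width) != 1L ||
      !is.finite(half_width) || half_width < 0 || half_width > 0.5) {
    stop("`half_width` must lie in [0, 0.5]")
  }
  interval <- abstention_interval(anchor, half_width)
  pred <- classify_with_abstention(xy$scores, interval)
  conf <- count_confusion(xy$labels, pred)
  list(mcc = mcc(conf), size_fraction = size_fraction(conf))
}

# Accept either (scores, labels) vectors or a labeled_scores data frame in
# the first argument.
resolve_scores_labels <- function(scores, labels) {
  if (is.data.frame(scores)) {
    if (!all(c("score", "label") %in% names(scores))) {
      stop("data-frame input must have columns `score` and `label`")
    }
    labels <- scores$label
    scores <- scores$score
  }
  if (is.null(labels)) stop("`labels` must be supplied")
  scores <- validate_scores(scores)
  labels <- canonicalize_labels(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length")
  }
  list(scores = scores, labels = labels)
}

#' Bundle scores and labels into a labeled score table
#'
#' The universal input of the optimizers: one row per sample with its
#' positive-class probability and binary ground-truth label.
#'
#' @param score Numeric vector of probabilities in \eqn{[0, 1]}.
#' @param label Binary labels aligned with `score`.
#' @param sample_id Optional sample identifiers; defaults to `1:n`.
#' @return A data frame of class `labeled_scores` with columns `sample_id`,
#'   `score`, `label`.
#' @export
labeled_scores <- function(score, label, sample_id = NULL) {
  score <- validate_scores(score)
  label <- canonicalize_labels(label)
  if (length(score) != length(label)) {
    stop("score and label differ in length")
  }
  if (is.null(sample_id)) sample_id <- seq_along(score)
  if (length(sample_id) != length(score)) {
    stop("sample_id differs in length from score")
  }
  structure(
    data.frame(sample_id = sample_id, score = score, label = label,
               stringsAsFactors = FALSE),
    class = c("labeled_scores", "data.frame")
  )
}
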