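# Confusion counting with a reject option, MCC, and coverage.
#
# Predictions are trinary: 1 (positive), 0 (negative), or NA (rejected).
# Ground-truth labels are strictly binary and may never carry the reject
# symbol.

#' Construct a confusion table with a reject count
#'
#' A 2x2 confusion matrix (true/false positives and negatives) extended with
#' the number of samples on which the classifier abstained. All downstream
#' metrics ([mcc()], [size_fraction()]) are computed from this object.
#'
#' @param tp,tn,fp,fn Non-negative integer counts of true positives, true
#'   negatives, false positives, and false negatives among the classified
#'   samples.
#' @param rejected Non-negative integer count of rejected (abstained) samples.
#' @return An object of class `confusion_reject`: a list with fields `tp`,
#'   `tn`, `fp`, `fn`, `rejected`.
#' @seealso [count_confusion()] to tally one from labels and predictions.
#' @examples
#' confusion_reject(tp = 4, tn = 3, fp = 2, fn = 1, rejected = 5)
#' @export
confusion_reject <- function(tp, tn, fp, fn, rejected = 0) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn, rejected = rejected)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("all confusion counts must be finite and non-negative")
  }
  if (any(counts != round(counts))) {
    stop("confusion counts must be whole numbers")
  }
  structure(
    list(tp = as.numeric(tp), tn = as.numeric(tn), fp = as.numeric(fp),
         fn = as.numeric(fn), rejected = as.numeric(rejected)),
    class = "confusion_reject"
  )
}

#' @export
print.confusion_reject <- function(x, ...) {
  cat("Confusion table with reject option\n")
  cat(sprintf("  TP = %d  FN = %d\n  FP = %d  TN = %d\n  rejected = %d (of %d)\n",
              x$tp, x$fn, x$fp, x$tn, x$rejected,
              x$tp + x$tn + x$fp + x$fn + x$rejected))
  invisible(x)
}

# Validate and coerce ground-truth labels to an integer 0/1 vector.
# Accepts numeric 0/1, logical, or a factor/character with exactly the
# values "0"/"1"; anything else must be mapped at ingestion (see
# read_scores(), argument `positive`).
canonicalize_labels <- function(labels) {
  if (anyNA(labels)) {
    stop("labels must not contain NA (the reject symbol is only valid in predictions)")
  }
  if (is.logical(labels)) {
    return(as.integer(labels))
  }
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    if (!all(labels %in% c("0", "1"))) {
      stop("character labels must be \"0\"/\"1\"; map other encodings at ingestion")
    }
    return(as.integer(labels))
  }
  if (!is.numeric(labels) || !all(labels %in% c(0, 1))) {
    stop("labels must be binary (0 = negative/control, 1 = positive/case)")
  }
  as.integer(labels)
}

#' Count a confusion table in the presence of a reject option
#'
#' Tallies TP/TN/FP/FN over the classified samples of a trichotomized
#' prediction vector and counts the rejected samples separately. A rejected
#' prediction is encoded as `NA` and contributes to the `rejected` count
#' regardless of its true label.
#'
#' @param labels Binary ground-truth labels (0/1, logical, or "0"/"1");
#'   must contain no `NA`.
#' @param predictions Vector of the same length over `{0, 1, NA}`; `NA`
#'   marks an abstained sample.
#' @return A [confusion_reject()] object; its five counts sum to
#'   `length(labels)`.
#' @examples
#' count_confusion(c(1, 0, 1, 0), c(1, 0, NA, NA))
#' @export
count_confusion <- function(labels, predictions) {
  if (length(labels) == 0L) stop("labels must be nonempty")
  if (length(labels) != length(predictions)) {
    stop(sprintf("labels (%d) and predictions (%d) differ in length",
                 length(labels), length(predictions)))
  }
  labels <- canonicalize_labels(labels)
  pred <- predictions
  if (is.logical(pred)) pred <- as.integer(pred)
  if (!is.numeric(pred) || !all(pred %in% c(0, 1) | is.na(pred))) {
    stop("predictions must take values in {0, 1, NA}")
  }
  kept <- !is.na(pred)
  confusion_reject(
    tp = sum(kept & pred == 1 & labels == 1, na.rm = TRUE),
    tn = sum(kept & pred == 0 & labels == 0, na.rm = TRUE),
    fp = sum(kept & pred == 1 & labels == 0, na.rm = TRUE),
    fn = sum(kept & pred == 0 & labels == 1, na.rm = TRUE),
    rejected = sum(!kept)
  )
}

# Shared MCC arithmetic; works on counts or on population rates (the formula
# is scale-invariant). Any zero factor in the denominator yields 0 by
# convention, which keeps the objective well-defined when abstention empties
# a predicted or true class.
mcc_formula <- function(tp, tn, fp, fn) {
  s1 <- tp + fp
  s2 <- tp + fn
  s3 <- tn + fp
  s4 <- tn + fn
  if (s1 == 0 || s2 == 0 || s3 == 0 || s4 == 0) {
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(s1 * s2 * s3 * s4)
}

#' Matthews correlation coefficient of the classified samples
#'
#' Computes
#' \deqn{\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' from a [confusion_reject()] object. The rejected count is ignored: MCC
#' measures correlation between truth and prediction among the samples the
#' classifier actually labeled. If any factor of the denominator is zero
#' (an empty predicted or true class, including total abstention), the MCC
#' is defined as 0.
#'
#' @param x A `confusion_reject` object.
#' @return A number in \eqn{[-1, 1]}.
#' @examples
#' mcc(confusion_reject(4, 3, 2, 1))  # 10 / sqrt(600)
#' @export
mcc <- function(x) {
  if (!inherits(x, "confusion_reject")) {
    stop("`x` must be a confusion_reject object; see confusion_reject()")
  }
  mcc_formula(x$tp, x$tn, x$fp, x$fn)
}

#' Fraction of samples classified (coverage)
#'
#' The fractional size of the classified set: 0 means every sample was
#' rejected, 1 means no abstention at all.
#'
#' @param x A `confusion_reject` object with a positive total count.
#' @return A number in \eqn{[0, 1]}.
#' @examples
#' size_fraction(confusion_reject(1, 1, 0, 0, rejected = 2))  # 0.5
#' @export
size_fraction <- function(x) {
  if (!inherits(x, "confusion_reject")) {
    stop("`x` must be a confusion_reject object; see confusion_reject()")
  }
  classified <- x$tp + x$tn + x$fp + x$fn
  total <- classified + x$rejected
  if (total == 0) stop("total sample count is zero")
  classified / total
}
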