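# End-to-end pipeline: stratified split, pluggable probabilistic classifier,
# none / symmetric / asymmetric abstention, and a three-row report.

#' Stratified hold-out split
#'
#' Splits sample indices into train and test sets while preserving the class
#' proportions to within one sample per class. Each class's training share is
#' `round(train_fraction * n_class)`, clamped so that both splits contain
#' both classes.
#'
#' @param labels Binary labels; each class needs at least 2 samples.
#' @param train_fraction Fraction of each class assigned to training, in
#'   (0, 1).
#' @param seed Integer seed.
#' @return A list with sorted integer vectors `train` and `test`; disjoint
#'   and exhaustive.
#' @examples
#' stratified_split(c(rep(1, 20), rep(0, 80)), train_fraction = 0.4, seed = 1)
#' @export
stratified_split <- function(labels, train_fraction, seed = 1) {
  labels <- canonicalize_labels(labels)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie strictly in (0, 1)")
  }
  train <- integer(0)
  for (cls in c(0L, 1L)) {
    idx <- which(labels == cls)
    if (length(idx) < 2L) {
      stop(sprintf("class %d has fewer than 2 samples; cannot split", cls))
    }
    n_train <- round(train_fraction * length(idx))
    n_train <- max(1L, min(length(idx) - 1L, n_train))
    picked <- withr::with_seed(seed + cls,
                               sample(idx, n_train, replace = FALSE))
    train <- c(train, picked)
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Logistic-regression base classifier
#'
#' The bundled default probabilistic classifier: a plain logistic model fit
#' with [stats::glm()]. Any classifier exposing the same two-function
#' contract can be plugged into [run_experiment()]: `fit(x, y)` returns a
#' model object and `prob(model, x)` returns positive-class probabilities in
#' \eqn{[0, 1]} — the abstention optimizers themselves are
#' classifier-agnostic.
#'
#' @return A list of class `abstention_classifier` with elements `name`,
#'   `fit`, and `prob`.
#' @export
logistic_classifier <- function() {
  structure(
    list(
      name = "logistic",
      fit = function(x, y) {
        dat <- as.data.frame(x)
        dat$.y <- y
        suppressWarnings(
          stats::glm(.y ~ ., data = dat, family = stats::binomial()))
      },
      prob = function(model, x) {
        p <- suppressWarnings(
          stats::predict(model, newdata = as.data.frame(x),
                         type = "response"))
        as.numeric(p)
      }
    ),
    class = "abstention_classifier"
  )
}

#' Configuration for an abstention experiment
#'
#' @param train_fraction Fraction of data used for training the base
#'   classifier (documented presets: 0.4 and 0.5, but any value in (0, 1)).
#' @param scenario `"imbalanced"` (use the data as is) or `"balanced"`
#'   (down-sample the majority class first, before splitting).
#' @param grid A [grid_spec()] shared by both optimizers.
#' @param split_seed,balance_seed Seeds for the stratified split and the
#'   balancing down-sample.
#' @param classifier A pluggable classifier; see [logistic_classifier()].
#' @param select_fraction Optional fraction of the non-training data held out
#'   for interval selection (three-way split). By default (`NULL`) intervals
#'   are selected on the test scores themselves; note this tunes on test data
#'   and biases the reported MCC upward, so set `select_fraction` for
#'   unbiased reporting.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(train_fraction = 0.4,
                              scenario = c("imbalanced", "balanced"),
                              grid = grid_spec(),
                              split_seed = 1, balance_seed = 1,
                              classifier = logistic_classifier(),
                              select_fraction = NULL) {
  scenario <- match.arg(scenario)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie strictly in (0, 1)")
  }
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.list(classifier) || !is.function(classifier$fit) ||
      !is.function(classifier$prob)) {
    stop("`classifier` must provide fit(x, y) and prob(model, x)")
  }
  if (!is.null(select_fraction) &&
      (select_fraction <= 0 || select_fraction >= 1)) {
    stop("`select_fraction` must lie strictly in (0, 1) or be NULL")
  }
  structure(
    list(train_fraction = train_fraction, scenario = scenario, grid = grid,
         split_seed = as.integer(split_seed),
         balance_seed = as.integer(balance_seed),
         classifier = classifier, select_fraction = select_fraction),
    class = "experiment_config"
  )
}

#' Run a full abstention experiment
#'
#' From a feature table: optionally balance (down-sample the majority class),
#' stratified-split, train the base classifier on the training split, score
#' the test split, then evaluate no abstention, the best symmetric interval,
#' and the best asymmetric interval on the test scores. From a
#' [labeled_scores()] table: skip splitting and training and optimize on the
#' scores directly (balancing still applies in the balanced scenario).
#'
#' @param data Either a feature data frame with a `label` column (and an
#'   optional `sample_id` column) or a [labeled_scores()] data frame.
#' @param cfg An [experiment_config()].
#' @return An `abstention_report`: a data frame with one row per method
#'   (`none`, `symmetric`, `asymmetric`) and columns `method`, `mcc`,
#'   `rejected_fraction`, `lower`, `upper`, `anchor`, `half_width` (interval
#'   columns are `NA` for `none`). The full optimizer results are attached as
#'   attribute `"fits"`, the evaluated indices as `"indices"`.
#' @examples
#' feats <- simulate_features(feature_sim_config(n = 200, seed = 11))
#' run_experiment(feats, experiment_config(train_fraction = 0.5))
#' @export
run_experiment <- function(data, cfg = experiment_config()) {
  stopifnot(inherits(cfg, "experiment_config"))
  is_scores <- inherits(data, "labeled_scores") ||
    (is.data.frame(data) && all(c("score", "label") %in% names(data)))
  if (!is.data.frame(data) || !"label" %in% names(data)) {
    stop("`data` must be a data frame with a `label` column")
  }
  labels_all <- canonicalize_labels(data$label)

  idx <- seq_len(nrow(data))
  if (cfg$scenario == "balanced") {
    idx <- downsample_balanced(labels_all, seed = cfg$balance_seed)
    data <- data[idx, , drop = FALSE]
    labels_all <- labels_all[idx]
  }

  if (is_scores) {
    scores <- validate_scores(data$score)
    labels <- labels_all
    eval_idx <- idx
  } else {
    feat_cols <- setdiff(names(data), c("label", "sample_id"))
    if (length(feat_cols) == 0L) stop("no feature columns found")
    split <- stratified_split(labels_all, cfg$train_fraction,
                              seed = cfg$split_seed)
    x <- data[feat_cols]
    model <- cfg$classifier$fit(x[split$train, , drop = FALSE],
                                labels_all[split$train])
    scores <- cfg$classifier$prob(model, x[split$test, , drop = FALSE])
    if (length(scores) != length(split$test) || anyNA(scores) ||
        any(scores < 0 | scores > 1)) {
      stop("classifier violated the probability contract: ",
           "one probability in [0, 1] per test sample is required")
    }
    labels <- labels_all[split$test]
    eval_idx <- idx[split$test]
  }

  # optional three-way split: select intervals on one part of the held-out
  # data, report on the remainder
  if (!is.null(cfg$select_fraction)) {
    sel <- stratified_split(labels, cfg$select_fraction,
                            seed = cfg$split_seed + 97L)
    sel_scores <- scores[sel$train]
    sel_labels <- labels[sel$train]
    scores <- scores[sel$test]
    labels <- labels[sel$test]
    eval_idx <- eval_idx[sel$test]
  } else {
    sel_scores <- scores
    sel_labels <- labels
  }

  fit_sym <- fit_symmetric(sel_scores, sel_labels, grid = cfg$grid)
  fit_asym <- fit_asymmetric(sel_scores, sel_labels, grid = cfg$grid)

  eval_interval <- function(interval) {
    conf <- count_confusion(labels,
                            classify_with_abstention(scores, interval))
    c(mcc = mcc(conf), rejected = 1 - size_fraction(conf))
  }
  none <- eval_interval(abstention_interval(0, 0))
  sym <- eval_interval(fit_sym$interval)
  asym <- eval_interval(fit_asym$interval)

  report <- data.frame(
    method = c("none", "symmetric", "asymmetric"),
    mcc = c(none["mcc"], sym["mcc"], asym["mcc"]),
    rejected_fraction = c(0, sym["rejected"], asym["rejected"]),
    lower = c(NA, fit_sym$interval$lower, fit_asym$interval$lower),
    upper = c(NA, fit_sym$interval$upper, fit_asym$interval$upper),
    anchor = c(NA, fit_sym$best$anchor, fit_asym$best$anchor),
    half_width = c(NA, fit_sym$best$half_width, fit_asym$best$half_width),
    stringsAsFactors = FALSE
  )
  rownames(report) <- NULL
  structure(report,
            class = c("abstention_report", "data.frame"),
            fits = list(symmetric = fit_sym, asymmetric = fit_asym),
            indices = eval_idx,
            scenario = cfg$scenario)
}

#' Serialize an abstention report to JSON
#'
#' Writes the three-row report at full floating-point precision; reading it
#' back with [read_report()] reproduces the data frame exactly.
#'
#' @param report An `abstention_report` from [run_experiment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "abstention_report"))
  out <- list(scenario = attr(report, "scenario") %||% NA_character_,
              rows = as.data.frame(report))
  # 17 significant digits: enough for exact double round-trip
  jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = I(17), na = "null")
  invisible(path)
}

#' Read an abstention report written by [write_report()]
#'
#' @param path JSON file path.
#' @return An `abstention_report` data frame.
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  rows <- raw$rows
  num_cols <- c("mcc", "rejected_fraction", "lower", "upper", "anchor",
                "half_width")
  for (cl in num_cols) rows[[cl]] <- as.numeric(rows[[cl]])
  structure(rows[c("method", num_cols)],
            class = c("abstention_report", "data.frame"),
            scenario = if (is.null(raw$scenario) || is.na(raw$scenario)) NULL
                       else raw$scenario)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Format an abstention report as an aligned text table
#'
#' Human-readable view with 3-decimal rounding; `band_rejected` replaces the
#' exact rejected fraction with a "< k%" band (the nearest of 1%, 5%, 10%,
#' 25%, 50%, 100% from above), a display convention only — the exact
#' fractions stay in the report itself.
#'
#' @param report An `abstention_report`.
#' @param band_rejected Use "< k%" banding instead of exact percentages.
#' @return A character vector of lines.
#' @export
format_report <- function(report, band_rejected = FALSE) {
  stopifnot(inherits(report, "abstention_report"))
  rej <- if (band_rejected) {
    bands <- c(0.01, 0.05, 0.10, 0.25, 0.50, 1)
    vapply(report$rejected_fraction, function(r) {
      if (r == 0) "0%" else
        sprintf("< %g%%", 100 * bands[which(r <= bands)[1]])
    }, character(1))
  } else {
    sprintf("%.1f%%", 100 * report$rejected_fraction)
  }
  interval <- ifelse(is.na(report$lower), "-",
                     sprintf("[%.3f, %.3f]", report$lower, report$upper))
  lines <- sprintf("%-12s %7s %9s  %s",
                   report$method, sprintf("%.3f", report$mcc), rej, interval)
  c(sprintf("%-12s %7s %9s  %s", "Abstention", "MCC", "Rejected", "Interval"),
    lines)
}

#' @export
print.abstention_report <- function(x, ...) {
  scen <- attr(x, "scenario")
  if (!is.null(scen)) cat(sprintf("Scenario: %s\n", scen))
  cat(format_report(x), sep = "\n")
  invisible(x)
}
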