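# Synthetic labeled scores and feature tables emulating imbalanced binary
# biomedical data, plus a closed-form population oracle for the optimizers.

#' Configuration for simulated classifier scores
#'
#' Scores are drawn from two class-conditional Beta distributions on
#' \eqn{[0, 1]} — Beta is supported on the probability scale, bends to any
#' skew, and has a closed-form CDF, which the population oracle
#' ([population_objective()]) exploits. The defaults emulate a decent but
#' imperfect classifier on heavily imbalanced data: cases score Beta(8, 2)
#' (mean 0.8), controls Beta(2, 8) (mean 0.2), with both tails overlapping
#' around the 0.5 decision boundary, and roughly one sample in ten a case —
#' the imbalance typical of screening-type biomedical datasets.
#'
#' @param n Number of samples (\eqn{\ge 2}).
#' @param positive_fraction Probability that a sample is a case, in (0, 1).
#' @param neg_shape,pos_shape Length-2 vectors of positive Beta shape
#'   parameters for controls and cases.
#' @param seed Integer seed; every draw from this configuration is
#'   reproducible.
#' @return An object of class `score_sim_config`.
#' @export
score_sim_config <- function(n = 1000, positive_fraction = 0.1,
                             neg_shape = c(2, 8), pos_shape = c(8, 2),
                             seed = 1) {
  if (!is.numeric(n) || length(n) != 1L || n < 2) stop("`n` must be >= 2")
  if (!is.numeric(positive_fraction) || length(positive_fraction) != 1L ||
      positive_fraction <= 0 || positive_fraction >= 1) {
    stop("`positive_fraction` must lie strictly in (0, 1)")
  }
  check_shape <- function(s, what) {
    if (!is.numeric(s) || length(s) != 2L || any(!is.finite(s)) ||
        any(s <= 0)) {
      stop(sprintf("`%s` must be two positive Beta shape parameters", what))
    }
  }
  check_shape(neg_shape, "neg_shape")
  check_shape(pos_shape, "pos_shape")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single integer")
  }
  structure(
    list(n = as.integer(n), positive_fraction = positive_fraction,
         neg_shape = as.numeric(neg_shape), pos_shape = as.numeric(pos_shape),
         seed = as.integer(seed)),
    class = "score_sim_config"
  )
}

#' Simulate labeled classifier scores
#'
#' Labels are Bernoulli draws with the configured positive fraction; scores
#' come from the class-conditional Beta distributions. Bit-reproducible under
#' the configuration's seed.
#'
#' @param cfg A [score_sim_config()].
#' @return A [labeled_scores()] data frame with `cfg$n` rows.
#' @examples
#' head(simulate_scores(score_sim_config(n = 100, seed = 42)))
#' @export
simulate_scores <- function(cfg) {
  stopifnot(inherits(cfg, "score_sim_config"))
  withr::with_seed(cfg$seed, {
    label <- stats::rbinom(cfg$n, 1L, cfg$positive_fraction)
    score <- numeric(cfg$n)
    n_pos <- sum(label == 1L)
    score[label == 1L] <- stats::rbeta(n_pos, cfg$pos_shape[1], cfg$pos_shape[2])
    score[label == 0L] <- stats::rbeta(cfg$n - n_pos,
                                       cfg$neg_shape[1], cfg$neg_shape[2])
  })
  labeled_scores(score, label)
}

#' Population value of the abstention objective
#'
#' The expected MCC x coverage of an abstention interval under the configured
#' Beta mixture, computed in closed form from Beta CDF values rather than by
#' simulation. Writing \eqn{\pi} for the positive fraction, \eqn{F_1, F_0}
#' for the case/control score CDFs, and \eqn{[L, U]} for the (clipped)
#' interval, the population confusion rates are
#' \deqn{TP = \pi(1 - F_1(U)),\; FN = \pi F_1(L),\;
#'       FP = (1-\pi)(1 - F_0(U)),\; TN = (1-\pi) F_0(L),}
#' coverage is their sum, and the MCC formula (with the same
#' zero-denominator convention as [mcc()]) is applied to the rates directly
#' — it is scale-invariant. Serves as the independent oracle for
#' parameter-recovery checks on the grid-search optimizers.
#'
#' @param cfg A [score_sim_config()]; its `n` and `seed` are ignored.
#' @param anchor,half_width Interval parameters; bounds are clipped to
#'   \eqn{[0, 1]} silently (the population is supported there).
#' @return The expected objective, a number in \eqn{[-1, 1]}.
#' @examples
#' population_objective(score_sim_config(), anchor = 0, half_width = 0.05)
#' @export
population_objective <- function(cfg, anchor = 0, half_width = 0) {
  stopifnot(inherits(cfg, "score_sim_config"))
  if (!is.numeric(half_width) || half_width < 0) {
    stop("`half_width` must be >= 0")
  }
  L <- min(1, max(0, 0.5 + anchor - half_width))
  U <- min(1, max(0, 0.5 + anchor + half_width))
  p <- cfg$positive_fraction
  tp <- p * (1 - stats::pbeta(U, cfg$pos_shape[1], cfg$pos_shape[2]))
  fn <- p * stats::pbeta(L, cfg$pos_shape[1], cfg$pos_shape[2])
  fp <- (1 - p) * (1 - stats::pbeta(U, cfg$neg_shape[1], cfg$neg_shape[2]))
  tn <- (1 - p) * stats::pbeta(L, cfg$neg_shape[1], cfg$neg_shape[2])
  coverage <- tp + tn + fp + fn
  if (coverage <= 0) return(0)
  mcc_formula(tp, tn, fp, fn) * coverage
}

#' Configuration for simulated feature tables
#'
#' Two isotropic Gaussian point clouds whose class centroids are
#' `class_separation` apart in every feature, with noise scale
#' `noise_scale`; a stand-in for real tabular biomedical data when exercising
#' the full train/score/abstain pipeline.
#'
#' @param n Number of samples (\eqn{\ge 4}).
#' @param n_features Number of features (\eqn{\ge 1}).
#' @param positive_fraction Case probability in (0, 1).
#' @param class_separation Per-feature centroid distance, \eqn{\ge 0}.
#' @param noise_scale Gaussian noise standard deviation, \eqn{> 0}.
#' @param seed Integer seed.
#' @return An object of class `feature_sim_config`.
#' @export
feature_sim_config <- function(n = 200, n_features = 5,
                               positive_fraction = 0.5,
                               class_separation = 2, noise_scale = 1,
                               seed = 1) {
  if (!is.numeric(n) || n < 4) stop("`n` must be >= 4")
  if (!is.numeric(n_features) || n_features < 1) {
    stop("`n_features` must be >= 1")
  }
  if (positive_fraction <= 0 || positive_fraction >= 1) {
    stop("`positive_fraction` must lie strictly in (0, 1)")
  }
  if (class_separation < 0) stop("`class_separation` must be >= 0")
  if (noise_scale <= 0) stop("`noise_scale` must be > 0")
  structure(
    list(n = as.integer(n), n_features = as.integer(n_features),
         positive_fraction = positive_fraction,
         class_separation = class_separation, noise_scale = noise_scale,
         seed = as.integer(seed)),
    class = "feature_sim_config"
  )
}

#' Simulate a feature table with binary labels
#'
#' @param cfg A [feature_sim_config()].
#' @return A data frame with columns `sample_id`, `f1` ... `fk`, `label`.
#' @export
simulate_features <- function(cfg) {
  stopifnot(inherits(cfg, "feature_sim_config"))
  withr::with_seed(cfg$seed, {
    label <- stats::rbinom(cfg$n, 1L, cfg$positive_fraction)
    x <- matrix(stats::rnorm(cfg$n * cfg$n_features, sd = cfg$noise_scale),
                nrow = cfg$n)
    x <- x + label * cfg$class_separation
  })
  colnames(x) <- paste0("f", seq_len(cfg$n_features))
  out <- data.frame(sample_id = seq_len(cfg$n), x, label = label)
  out
}

#' Down-sample the majority class to balance a dataset
#'
#' Keeps every minority-class sample and a uniform, without-replacement
#' subsample of the majority class of equal size. Already balanced input is
#' returned whole.
#'
#' @param labels Binary labels; both classes must be present.
#' @param seed Integer seed for the majority-class subsample.
#' @return Sorted integer indices into `labels` with equal class counts.
#' @examples
#' downsample_balanced(c(rep(0, 8), rep(1, 2)), seed = 3)
#' @export
downsample_balanced <- function(labels, seed = 1) {
  labels <- canonicalize_labels(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to balance")
  }
  if (n_pos == n_neg) return(seq_along(labels))
  minority <- if (n_pos < n_neg) 1L else 0L
  idx_min <- which(labels == minority)
  idx_maj <- which(labels != minority)
  keep_maj <- withr::with_seed(seed,
                               sample(idx_maj, length(idx_min),
                                      replace = FALSE))
  sort(c(idx_min, keep_maj))
}
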