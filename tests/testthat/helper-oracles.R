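# Brute-force oracles and random-instance generators shared across tests.
# Everything here is written independently of the package internals: plain
# loops and inline arithmetic, so the optimizers and metrics have something
# honest to disagree with.

# Overlapping Beta-mixture scores; deliberately not simulate_scores().
random_instance <- function(seed, n = 200, positive_fraction = 0.3) {
  withr::with_seed(seed, {
    label <- stats::rbinom(n, 1, positive_fraction)
    score <- ifelse(label == 1,
                    stats::rbeta(n, 5, 2.5),
                    stats::rbeta(n, 2.5, 5))
  })
  list(score = score, label = label)
}

# Inline trichotomize + confusion + MCC, no package calls.
oracle_cost <- function(score, label, anchor, half_width) {
  L <- max(0, min(1, 0.5 + anchor - half_width))
  U <- max(0, min(1, 0.5 + anchor + half_width))
  pred <- rep(NA_integer_, length(score))
  pred[score <= L] <- 0L
  pred[score >= U] <- 1L
  kept <- !is.na(pred)
  tp <- sum(kept & pred == 1 & label == 1)
  tn <- sum(kept & pred == 0 & label == 0)
  fp <- sum(kept & pred == 1 & label == 0)
  fn <- sum(kept & pred == 0 & label == 1)
  m <- if ((tp + fp) == 0 || (tp + fn) == 0 || (tn + fp) == 0 ||
           (tn + fn) == 0) 0
       else (tp * tn - fp * fn) /
            sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  sz <- (tp + tn + fp + fn) / length(score)
  list(mcc = m, size_fraction = sz, objective = m * sz)
}

# Exhaustive double loop with the documented tie-break: highest objective,
# then smallest half-width, then anchor nearest zero, then lower anchor.
oracle_fit <- function(score, label, half_widths, anchors) {
  best <- NULL
  for (h in half_widths) {
    for (a in anchors) {
      cand <- oracle_cost(score, label, a, h)
      cand$half_width <- h
      cand$anchor <- a
      replace <- is.null(best) ||
        cand$objective > best$objective ||
        (cand$objective == best$objective &&
           (cand$half_width < best$half_width ||
              (cand$half_width == best$half_width &&
                 (abs(cand$anchor) < abs(best$anchor) ||
                    (abs(cand$anchor) == abs(best$anchor) &&
                       cand$anchor < best$anchor)))))
      if (replace) best <- cand
    }
  }
  best
}

# O(n^2) pairwise-domination loop over (mcc, size_fraction).
oracle_pareto <- function(m, s) {
  n <- length(m)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (m[j] >= m[i] && s[j] >= s[i] && (m[j] > m[i] || s[j] > s[i])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  keep
}

random_confusion <- function() {
  counts <- sample(0:40, 5, replace = TRUE)
  confusion_reject(counts[1], counts[2], counts[3], counts[4], counts[5])
}

# Population objective evaluated at every grid point, with the neighborhood
# of the optimum (one step in either coordinate) defining the acceptable
# objective gap for parameter-recovery checks.
population_grid <- function(cfg, grid) {
  hws <- grid_half_widths(grid)
  anchors <- grid_anchors(grid)
  obj <- outer(seq_along(hws), seq_along(anchors),
               Vectorize(function(i, j)
                 population_objective(cfg, anchors[j], hws[i])))
  opt_idx <- which(obj == max(obj), arr.ind = TRUE)[1, ]
  i <- opt_idx[1]; j <- opt_idx[2]
  nb <- c(obj[i, j],
          if (i > 1) obj[i - 1, j], if (i < length(hws)) obj[i + 1, j],
          if (j > 1) obj[i, j - 1], if (j < length(anchors)) obj[i, j + 1])
  list(objective = obj, optimum = max(obj), floor = min(nb),
       half_widths = hws, anchors = anchors)
}
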