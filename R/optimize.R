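# Grid-search optimizers for the abstention interval, and Pareto-front
# extraction over (MCC, coverage).

#' Specify the search grid for the abstention optimizers
#'
#' The half-width grid is the half-open arithmetic sequence
#' `interval_low, interval_low + interval_step, ...` strictly below
#' `interval_high`; the defaults (0, 0.16, 0.01) evaluate the 16 half-widths
#' 0.00-0.15, i.e. from no abstention up to an interval covering 30% of the
#' probability range. The anchor grid holds `num_anchors` evenly spaced
#' values from `-anchor_width` to `+anchor_width` including both endpoints;
#' with the default even count of 20, zero is not on that grid, so
#' `include_zero_anchor = TRUE` (the default) injects it, guaranteeing the
#' asymmetric search contains the symmetric one as a subset. Set it to
#' `FALSE` for the strict 20-anchor replication profile.
#'
#' @param interval_low,interval_high,interval_step Half-width grid bounds
#'   and step; `0 <= interval_low < interval_high <= 0.5`, `interval_step > 0`.
#' @param anchor_width Maximum absolute anchor; anchors span
#'   `[-anchor_width, anchor_width]`.
#' @param num_anchors Number of evenly spaced anchors (endpoints included).
#' @param include_zero_anchor Inject anchor 0 when the even spacing skips it.
#' @return An object of class `grid_spec`.
#' @seealso [grid_half_widths()], [grid_anchors()]
#' @export
grid_spec <- function(interval_low = 0, interval_high = 0.16,
                      interval_step = 0.01, anchor_width = 0.2,
                      num_anchors = 20, include_zero_anchor = TRUE) {
  if (!(interval_low >= 0 && interval_low < interval_high &&
        interval_high <= 0.5)) {
    stop("need 0 <= interval_low < interval_high <= 0.5")
  }
  if (interval_step <= 0) stop("`interval_step` must be > 0")
  if (num_anchors < 1) stop("`num_anchors` must be >= 1")
  if (anchor_width < 0) stop("`anchor_width` must be >= 0")
  structure(
    list(interval_low = interval_low, interval_high = interval_high,
         interval_step = interval_step, anchor_width = anchor_width,
         num_anchors = as.integer(num_anchors),
         include_zero_anchor = isTRUE(include_zero_anchor)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "Grid: half-widths [%g, %g) step %g (%d values); %d anchors on [%g, %g]%s\n",
    x$interval_low, x$interval_high, x$interval_step,
    length(grid_half_widths(x)), length(grid_anchors(x)),
    -x$anchor_width, x$anchor_width,
    if (x$include_zero_anchor) " incl. 0" else ""))
  invisible(x)
}

#' Half-width values of a search grid
#'
#' @param grid A [grid_spec()].
#' @return Numeric vector of half-widths in `[interval_low, interval_high)`.
#' @export
grid_half_widths <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  n_steps <- floor((grid$interval_high - grid$interval_low) /
                     grid$interval_step + 1e-9)
  hw <- grid$interval_low + grid$interval_step * (0:n_steps)
  hw[hw < grid$interval_high - 1e-9]
}

#' Anchor values of a search grid
#'
#' @param grid A [grid_spec()].
#' @return Numeric vector of anchors, sorted ascending; includes 0 when
#'   `include_zero_anchor` is set and the even spacing skips it.
#' @export
grid_anchors <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  a <- if (grid$num_anchors == 1L) 0
       else seq(-grid$anchor_width, grid$anchor_width,
                length.out = grid$num_anchors)
  if (grid$include_zero_anchor && !any(abs(a) < 1e-12)) {
    a <- sort(c(a, 0))
  }
  a
}

# Evaluate the cost at every (half_width, anchor) combination; returns the
# tidy evaluation grid with one row per point.
evaluate_grid <- function(scores, labels, half_widths, anchors) {
  pts <- expand.grid(anchor = anchors, half_width = half_widths,
                     KEEP.OUT.ATTRS = FALSE)
  res <- vapply(seq_len(nrow(pts)), function(i) {
    cs <- abstention_cost(scores, labels,
                          anchor = pts$anchor[i],
                          half_width = pts$half_width[i])
    c(cs$mcc, cs$size_fraction)
  }, numeric(2))
  data.frame(
    half_width = pts$half_width,
    anchor = pts$anchor,
    mcc = res[1, ],
    size_fraction = res[2, ],
    objective = res[1, ] * res[2, ]
  )
}

# Deterministic argmax over the evaluation grid: highest objective, ties
# broken by smallest half-width (least abstention), then anchor nearest 0
# (most symmetric), then the lower anchor.
select_best <- function(grid_df) {
  ord <- order(-grid_df$objective, grid_df$half_width,
               abs(grid_df$anchor), grid_df$anchor)
  grid_df[ord[1L], , drop = FALSE]
}

new_abstention_fit <- function(grid_df, grid, mode) {
  best <- select_best(grid_df)
  structure(
    list(
      best = best,
      interval = abstention_interval(best$anchor, best$half_width),
      grid = grid_df,
      pareto_front = pareto_front(grid_df),
      mode = mode,
      grid_spec = grid
    ),
    class = "abstention_fit"
  )
}

#' Fit the best symmetric abstention interval
#'
#' One-dimensional grid search: evaluates [abstention_cost()] at anchor 0 for
#' every half-width of the grid and selects the point maximizing the
#' objective MCC x coverage. The no-abstention point (half-width 0) is part
#' of every default grid, so the selected objective can never fall below the
#' plain classifier's.
#'
#' @param scores Positive-class probabilities, or a [labeled_scores()] frame.
#' @param labels Binary labels (omit when `scores` is a data frame).
#' @param grid A [grid_spec()]; only its half-width component is used.
#' @return An object of class `abstention_fit` with fields `best` (one-row
#'   data frame: half_width, anchor, mcc, size_fraction, objective),
#'   `interval` (the corresponding [abstention_interval()]), `grid` (all
#'   evaluated points), `pareto_front`, `mode`, and `grid_spec`.
#' @examples
#' set.seed(1)
#' s <- simulate_scores(score_sim_config(n = 500, seed = 7))
#' fit_symmetric(s)
#' @export
fit_symmetric <- function(scores, labels = NULL, grid = grid_spec()) {
  xy <- resolve_scores_labels(scores, labels)
  hws <- grid_half_widths(grid)
  if (length(hws) == 0L) stop("the half-width grid is empty")
  new_abstention_fit(evaluate_grid(xy$scores, xy$labels, hws, 0), grid,
                     mode = "symmetric")
}

#' Fit the best asymmetric abstention interval
#'
#' Two-dimensional grid search over the Cartesian product of the half-width
#' grid and the anchor grid; the selected `(anchor, half_width)` maximizes
#' MCC x coverage. When the anchor grid contains 0, the symmetric search is a
#' subset, so the asymmetric objective is at least the symmetric one.
#'
#' @inheritParams fit_symmetric
#' @return An `abstention_fit`; see [fit_symmetric()].
#' @examples
#' s <- simulate_scores(score_sim_config(n = 500, seed = 7))
#' fit_asymmetric(s)
#' @export
fit_asymmetric <- function(scores, labels = NULL, grid = grid_spec()) {
  xy <- resolve_scores_labels(scores, labels)
  hws <- grid_half_widths(grid)
  anchors <- grid_anchors(grid)
  if (length(hws) == 0L || length(anchors) == 0L) {
    stop("the search grid is empty")
  }
  new_abstention_fit(evaluate_grid(xy$scores, xy$labels, hws, anchors), grid,
                     mode = "asymmetric")
}

#' @export
print.abstention_fit <- function(x, ...) {
  label <- paste0(toupper(substring(x$mode, 1, 1)), substring(x$mode, 2))
  cat(sprintf("%s abstention fit (%d grid points evaluated)\n",
              label, nrow(x$grid)))
  cat(sprintf("  best interval [%.3f, %.3f] (anchor %.4f, half-width %.3f)\n",
              x$interval$lower, x$interval$upper,
              x$best$anchor, x$best$half_width))
  cat(sprintf("  MCC %.3f, coverage %.3f, rejected %.1f%%, objective %.3f\n",
              x$best$mcc, x$best$size_fraction,
              100 * (1 - x$best$size_fraction), x$best$objective))
  cat(sprintf("  Pareto front: %d non-dominated point(s)\n",
              nrow(x$pareto_front)))
  invisible(x)
}

#' Pareto front of evaluated abstention settings
#'
#' MCC and coverage are conflicting goals: widening the interval can raise
#' the MCC of the classified samples but lowers the fraction classified. The
#' Pareto front is the set of evaluated points not strictly dominated in
#' `(mcc, size_fraction)` — a point dominates another if it is at least as
#' good in both coordinates and strictly better in one. The product
#' objective's argmax is always on (or tied with) the front.
#'
#' @param points A data frame with columns `mcc` and `size_fraction`, e.g.
#'   the `grid` of an [fit_symmetric()] / [fit_asymmetric()] result.
#' @return The non-dominated rows, sorted by `size_fraction` descending
#'   (ties by `mcc` descending).
#' @export
pareto_front <- function(points) {
  if (!is.data.frame(points) ||
      !all(c("mcc", "size_fraction") %in% names(points))) {
    stop("`points` must be a data frame with columns mcc and size_fraction")
  }
  n <- nrow(points)
  if (n == 0L) stop("`points` must be nonempty")
  m <- points$mcc
  s <- points$size_fraction
  dominated <- vapply(seq_len(n), function(i) {
    any(m >= m[i] & s >= s[i] & (m > m[i] | s > s[i]))
  }, logical(1))
  front <- points[!dominated, , drop = FALSE]
  front[order(-front$size_fraction, -front$mcc), , drop = FALSE]
}
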