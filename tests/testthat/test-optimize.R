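test_that("default grids have the documented cardinalities", {
  g <- grid_spec(include_zero_anchor = FALSE)
  expect_equal(grid_half_widths(g), seq(0, 0.15, by = 0.01))
  a <- grid_anchors(g)
  expect_length(a, 20)
  expect_equal(a[1], -0.2)
  expect_equal(a[20], 0.2)
  expect_false(any(a == 0))

  g0 <- grid_spec()  # zero anchor injected by default
  expect_length(grid_anchors(g0), 21)
  expect_true(any(grid_anchors(g0) == 0))

  expect_error(grid_spec(interval_low = 0.2, interval_high = 0.1))
  expect_error(grid_spec(interval_high = 0.6))
  expect_error(grid_spec(interval_step = 0))
  expect_error(grid_spec(num_anchors = 0))
})

test_that("symmetric fit evaluates the half-width grid at anchor zero", {
  inst <- random_instance(7)
  fit <- fit_symmetric(inst$score, inst$label)
  expect_equal(nrow(fit$grid), 16)
  expect_true(all(fit$grid$anchor == 0))
  expect_equal(fit$grid$half_width, seq(0, 0.15, by = 0.01))
  # interval centered at 0.5
  expect_equal(fit$interval$lower + fit$interval$upper, 1)
  expect_equal(fit$grid$objective, fit$grid$mcc * fit$grid$size_fraction)
})

test_that("perfectly separated scores select no abstention at all", {
  score <- c(seq(0.05, 0.35, length.out = 10), seq(0.65, 0.95, length.out = 10))
  label <- rep(c(0, 1), each = 10)
  fit <- fit_symmetric(score, label)
  expect_equal(fit$best$half_width, 0)
  expect_equal(fit$best$objective, 1)
  fit2 <- fit_asymmetric(score, label)
  expect_equal(fit2$best$half_width, 0)
  expect_equal(fit2$best$anchor, 0)  # tie-break prefers the symmetric point
})

test_that("asymmetric fit covers the full Cartesian grid", {
  inst <- random_instance(11)
  fit <- fit_asymmetric(inst$score, inst$label,
                        grid = grid_spec(include_zero_anchor = FALSE))
  expect_equal(nrow(fit$grid), 16 * 20)
  expect_equal(sort(unique(fit$grid$anchor)),
               seq(-0.2, 0.2, length.out = 20))
})

test_that("optimizers agree with an exhaustive brute-force search", {
  g <- grid_spec(include_zero_anchor = FALSE)
  hws <- grid_half_widths(g)
  anchors <- grid_anchors(g)
  for (seed in 1:20) {
    inst <- random_instance(seed)
    fa <- fit_asymmetric(inst$score, inst$label, grid = g)
    oa <- oracle_fit(inst$score, inst$label, hws, anchors)
    expect_equal(fa$best$half_width, oa$half_width)
    expect_equal(fa$best$anchor, oa$anchor)
    expect_equal(fa$best$objective, oa$objective)

    fs <- fit_symmetric(inst$score, inst$label, grid = g)
    os <- oracle_fit(inst$score, inst$label, hws, 0)
    expect_equal(fs$best$half_width, os$half_width)
    expect_equal(fs$best$objective, os$objective)
  }
})

test_that("asymmetric search restricted to anchor zero equals the symmetric fit", {
  inst <- random_instance(3)
  g1 <- grid_spec(num_anchors = 1, anchor_width = 0,
                  include_zero_anchor = TRUE)
  fa <- fit_asymmetric(inst$score, inst$label, grid = g1)
  fs <- fit_symmetric(inst$score, inst$label, grid = g1)
  expect_equal(fa$grid, fs$grid)
  expect_equal(fa$best, fs$best)
  expect_equal(fa$interval$lower, fs$interval$lower)
})

test_that("coverage shrinks and rejected sets nest as the interval widens", {
  for (seed in 1:100) {
    inst <- random_instance(seed, n = 50)
    anchor <- withr::with_seed(seed * 13, stats::runif(1, -0.15, 0.15))
    widths <- seq(0, 0.3, by = 0.05)
    prev_rejected <- integer(0)
    prev_size <- 1
    for (h in widths) {
      iv <- abstention_interval(anchor, h)
      pred <- classify_with_abstention(inst$score, iv)
      rejected <- which(is.na(pred))
      conf <- count_confusion(inst$label, pred)
      sz <- size_fraction(conf)
      expect_lte(sz, prev_size)
      expect_true(all(prev_rejected %in% rejected))
      prev_rejected <- rejected
      prev_size <- sz
    }
  }
})

test_that("identical inputs yield bit-identical optimization results", {
  inst <- random_instance(42)
  f1 <- fit_asymmetric(inst$score, inst$label)
  f2 <- fit_asymmetric(inst$score, inst$label)
  expect_identical(f1$grid, f2$grid)
  expect_identical(f1$best, f2$best)
  expect_identical(f1$pareto_front, f2$pareto_front)
})

test_that("pareto_front keeps exactly the non-dominated points", {
  pts <- data.frame(mcc = c(0.5, 0.9, 0.4), size_fraction = c(1.0, 0.8, 0.9))
  front <- pareto_front(pts)
  expect_equal(nrow(front), 2)
  expect_equal(front$mcc, c(0.5, 0.9))        # sorted by coverage desc
  expect_equal(front$size_fraction, c(1.0, 0.8))

  single <- data.frame(mcc = 0.3, size_fraction = 0.7)
  expect_equal(nrow(pareto_front(single)), 1)

  expect_error(pareto_front(data.frame(mcc = numeric(0),
                                       size_fraction = numeric(0))),
               "nonempty")
})

test_that("pareto_front matches a pairwise-domination oracle on random sets", {
  withr::with_seed(99, {
    for (rep in 1:5) {
      pts <- data.frame(mcc = round(stats::runif(100, -1, 1), 2),
                        size_fraction = round(stats::runif(100), 2))
      front <- pareto_front(pts)
      keep <- oracle_pareto(pts$mcc, pts$size_fraction)
      expect_equal(nrow(front), sum(keep))
      got <- front[order(front$mcc, front$size_fraction), ]
      want <- pts[keep, ][order(pts$mcc[keep], pts$size_fraction[keep]), ]
      expect_equal(got$mcc, want$mcc)
      expect_equal(got$size_fraction, want$size_fraction)
    }
  })
})

test_that("the objective argmax is never strictly dominated by the front", {
  for (seed in c(5, 17)) {
    inst <- random_instance(seed)
    fit <- fit_asymmetric(inst$score, inst$label)
    f <- fit$pareto_front
    strictly <- f$mcc > fit$best$mcc & f$size_fraction > fit$best$size_fraction
    expect_false(any(strictly))
  }
})
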