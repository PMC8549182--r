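test_that("stratified split preserves class proportions within one sample", {
  labels <- c(rep(1, 20), rep(0, 80))
  sp <- stratified_split(labels, train_fraction = 0.4, seed = 1)
  expect_equal(sum(labels[sp$train] == 1), 8)
  expect_equal(sum(labels[sp$train] == 0), 32)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0)

  # screening-shaped labels: 176 cases of 1831 at a 50% training share
  big <- c(rep(1, 176), rep(0, 1655))
  sp2 <- stratified_split(big, train_fraction = 0.5, seed = 2)
  expect_true(abs(sum(big[sp2$train] == 1) - 88) <= 1)
  expect_true(abs(sum(big[sp2$train] == 0) - 827.5) <= 1)

  expect_identical(stratified_split(labels, 0.4, seed = 9),
                   stratified_split(labels, 0.4, seed = 9))
  expect_error(stratified_split(c(1, 0, 0, 0), 0.5), "fewer than 2")
})

test_that("separable features give near-perfect MCC with almost no rejection", {
  feats <- simulate_features(
    feature_sim_config(n = 300, class_separation = 6, noise_scale = 1,
                       seed = 21))
  rep_ <- run_experiment(feats, experiment_config(train_fraction = 0.5))
  expect_equal(rep_$method, c("none", "symmetric", "asymmetric"))
  expect_true(all(rep_$mcc > 0.95))
  expect_true(all(rep_$rejected_fraction < 0.05))
})

test_that("signal-free features give MCC near zero", {
  feats <- simulate_features(
    feature_sim_config(n = 400, class_separation = 0, seed = 33))
  rep_ <- run_experiment(feats, experiment_config(train_fraction = 0.5))
  expect_lt(abs(rep_$mcc[rep_$method == "none"]), 0.3)
})

test_that("abstention never lowers the objective below the plain classifier", {
  for (seed in 1:5) {
    s <- simulate_scores(score_sim_config(n = 800, seed = seed))
    base <- abstention_cost(s$score, s$label, 0, 0)
    for (fit in list(fit_symmetric(s), fit_asymmetric(s))) {
      expect_gte(fit$best$objective, base$mcc * base$size_fraction)
    }
    rep_ <- run_experiment(s, experiment_config())
    none_mcc <- rep_$mcc[rep_$method == "none"]
    expect_gte(rep_$mcc[rep_$method == "symmetric"], none_mcc)
    expect_gte(rep_$mcc[rep_$method == "asymmetric"], none_mcc)
  }
})

test_that("report schema and invariants hold on score input", {
  s <- simulate_scores(score_sim_config(n = 500, seed = 3))
  rep_ <- run_experiment(s, experiment_config())
  expect_s3_class(rep_, "abstention_report")
  expect_named(rep_, c("method", "mcc", "rejected_fraction", "lower",
                       "upper", "anchor", "half_width"))
  none <- rep_[rep_$method == "none", ]
  expect_true(is.na(none$lower) && is.na(none$upper))
  expect_equal(none$rejected_fraction, 0)
  fits <- attr(rep_, "fits")
  expect_equal(rep_$rejected_fraction[rep_$method == "asymmetric"],
               1 - fits$asymmetric$best$size_fraction)
})

test_that("the balanced scenario evaluates a subset of the imbalanced data", {
  feats <- simulate_features(
    feature_sim_config(n = 500, positive_fraction = 0.2,
                       class_separation = 2, seed = 13))
  imb <- run_experiment(feats, experiment_config(train_fraction = 0.5,
                                                 scenario = "imbalanced"))
  bal <- run_experiment(feats, experiment_config(train_fraction = 0.5,
                                                 scenario = "balanced"))
  idx_bal <- downsample_balanced(feats$label, seed = 1)
  expect_true(all(attr(bal, "indices") %in% idx_bal))
  expect_lt(length(attr(bal, "indices")), length(attr(imb, "indices")))
})

test_that("reports round-trip through JSON exactly", {
  s <- simulate_scores(score_sim_config(n = 300, seed = 6))
  rep_ <- run_experiment(s, experiment_config())
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep_, path)
  back <- read_report(path)
  expect_identical(back$method, rep_$method)
  for (col in c("mcc", "rejected_fraction", "lower", "upper", "anchor",
                "half_width")) {
    expect_identical(back[[col]], rep_[[col]])
  }
  expect_equal(attr(back, "scenario"), attr(rep_, "scenario"))
})

test_that("a classifier breaking the probability contract is caught", {
  bad <- structure(list(name = "bad",
                        fit = function(x, y) NULL,
                        prob = function(model, x) rep(1.5, nrow(x))),
                   class = "abstention_classifier")
  feats <- simulate_features(feature_sim_config(n = 100, seed = 1))
  expect_error(
    run_experiment(feats, experiment_config(train_fraction = 0.5,
                                            classifier = bad)),
    "probability contract")
})

test_that("the three-way split option selects intervals off the test data", {
  s <- simulate_scores(score_sim_config(n = 2000, seed = 10))
  rep_ <- run_experiment(s, experiment_config(select_fraction = 0.5))
  expect_equal(nrow(rep_), 3)
  # reported on the held-back half only
  expect_lt(length(attr(rep_, "indices")), 2000 * 0.75)
})

test_that("banded report formatting rounds the rejected column up to a band", {
  s <- simulate_scores(score_sim_config(n = 500, seed = 3))
  rep_ <- run_experiment(s, experiment_config())
  txt <- format_report(rep_, band_rejected = TRUE)
  expect_length(txt, 4)
  expect_match(txt[1], "Abstention")
  expect_true(all(grepl("^(0%|< \\d+%)$",
                        sub(".*?(0%|< \\d+%).*", "\\1", txt[-1]))))
})
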