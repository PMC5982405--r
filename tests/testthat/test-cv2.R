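test_that("stratified splits keep class proportions and are reproducible", {
  label <- rep(c("responder", "non-responder"), c(8, 4))
  set.seed(61)
  sp <- stratified_split(label, B = 3)
  expect_equal(sum(label[sp$test] == "responder"), 2)
  expect_equal(sum(label[sp$test] == "non-responder"), 1)
  expect_setequal(c(sp$calibration, sp$test), seq_along(label))

  set.seed(99); a <- stratified_split(label, B = 3)
  set.seed(99); b <- stratified_split(label, B = 3)
  expect_identical(a, b)

  expect_error({set.seed(1); stratified_split(label, B = 11)},
               class = "plsvip_stratification_error")
  # B = 2 still represents both classes
  set.seed(62)
  sp2 <- stratified_split(label, B = 2)
  expect_equal(length(unique(label[sp2$test])), 2)
})

test_that("iterative VIP pruning recovers planted features and its stopping
           point matches an exhaustive grid evaluation", {
  sep <- make_separable(12, 12, J = 100, planted = 5, effect = 5, seed = 63)
  cfg <- cv2_config(n_iterations = 1, test_count = 4, seed = 1)
  set.seed(64)
  out <- iterative_vip_prune(sep$x, sep$y, cfg)
  # one split keeps every planted feature; the handful of chance-correlated
  # noise survivors are what the stability-frequency filter removes later
  expect_true(all(sprintf("F%03d", 1:5) %in% out$features))
  expect_lt(length(out$features), 20)
  # pruning may not cost cross-validated performance
  full_rmsecv <- out$path$rmsecv[out$path$threshold == 0]
  expect_lte(out$rmsecv, full_rmsecv * (1 + cfg$rmsecv_tolerance) + 1e-12)
  # oracle check: the returned threshold is the highest accepted one, and
  # acceptance in the recorded path follows the running-best tolerance rule
  path <- out$path
  best <- Inf
  for (i in seq_len(nrow(path))) {
    expect_equal(path$accepted[i],
                 path$rmsecv[i] <= best * (1 + cfg$rmsecv_tolerance) + 1e-12)
    if (path$accepted[i]) best <- min(best, path$rmsecv[i])
  }
  expect_equal(out$threshold, max(path$threshold[path$accepted]))
})

test_that("a threshold below every VIP selects all features, and pure noise
           still terminates with a usable model", {
  sep <- make_separable(8, 8, J = 20, planted = 2, effect = 4, seed = 65)
  cfg <- cv2_config(n_iterations = 1, test_count = 4,
                    vip_grid = 1e-6, seed = 1)
  set.seed(66)
  out <- iterative_vip_prune(sep$x, sep$y, cfg)
  expect_setequal(out$features, colnames(sep$x))

  set.seed(67)
  noise <- matrix(rnorm(24 * 50), 24, 50)
  y <- rep(c(1, -1), 12)
  out2 <- iterative_vip_prune(noise, y, cv2_config(n_iterations = 1,
                                                   test_count = 4))
  expect_gte(length(out2$features), 2)
  expect_true(is.finite(out2$rmsecv))
})

test_that("one CV2 iteration classifies separable held-out samples
           perfectly and honours small-arm splits", {
  gen <- recovery_dataset(seed = 68, n_features = 120, n_informative = 5)
  it <- run_cv2_iteration(gen$dataset, cv2_config(test_count = 8), seed = 5)
  expect_equal(it$misclassified, 0)
  expect_lte(length(it$test_ids), 8)
  expect_length(intersect(it$test_ids, it$calibration_ids), 0)

  # quetiapine-like arm: 14 patients, B = 2
  quet <- generate_dataset(synthetic_config(
    n_responders = 9, n_nonresponders = 5, n_features = 80,
    n_informative = 4, effect_size = 5, n_blank_features = 0,
    n_low_abundance = 0, seed = 69))
  it2 <- run_cv2_iteration(normalize_abundance(quet$dataset),
                           cv2_config(test_count = 2), seed = 6)
  expect_equal(it2$test_size, 2)
  expect_lte(it2$misclassified, 2)
})

test_that("under permuted labels test misclassification matches the
           no-signal rate", {
  # oracle: with no usable signal the classifier cannot beat the class
  # balance, so the expected per-sample error is roughly the minority share
  gen <- generate_dataset(synthetic_config(
    n_responders = 20, n_nonresponders = 10, n_features = 30,
    n_informative = 0, effect_size = 0, n_blank_features = 0,
    n_low_abundance = 0, seed = 70))
  ds <- normalize_abundance(gen$dataset)
  cfg <- cv2_config(n_iterations = 30, test_count = 6, seed = 71)
  ss <- run_stability_selection(ds, cfg)
  rate <- ss$misclassified_pct_mean / 100
  # minority fraction is 1/3; binomial sampling error over 30x6 predictions
  expect_gt(rate, 0.33 - 3 * sqrt(0.33 * 0.67 / 180))
  expect_lt(rate, 0.67)
})

test_that("stability selection is deterministic, consistent at one
           iteration, and monotone in the frequency threshold", {
  gen <- recovery_dataset(seed = 72, n_features = 80, n_informative = 4)
  cfg <- cv2_config(n_iterations = 5, test_count = 8, seed = 73)
  s1 <- run_stability_selection(gen$dataset, cfg)
  s2 <- run_stability_selection(gen$dataset, cfg)
  expect_identical(s1$frequency, s2$frequency)
  expect_identical(s1$stable_set, s2$stable_set)

  one <- run_stability_selection(gen$dataset,
                                 cv2_config(n_iterations = 1, test_count = 8,
                                            seed = 74))
  it <- one$iterations[[1]]
  expect_setequal(one$stable_set, it$selected)
  expect_equal(one$rmsecv_mean, it$rmsecv)
  expect_equal(one$n_lv_mean, it$n_lv)

  # raising the threshold never enlarges the stable set
  freq <- s1$frequency
  sets <- lapply(c(0.5, 0.8, 0.95, 1), function(th) names(freq)[freq >= th])
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})

test_that("permuting feature columns permutes selection frequencies
           identically", {
  gen <- recovery_dataset(seed = 75, n_features = 40, n_informative = 3)
  ds <- gen$dataset
  cfg <- cv2_config(n_iterations = 4, test_count = 8, seed = 76)
  base <- run_stability_selection(ds, cfg)

  set.seed(77)
  perm <- sample(ncol(ds$abundance))
  ds2 <- ds
  ds2$abundance <- ds$abundance[, perm]
  ds2$features <- ds$features[perm, ]
  permuted <- run_stability_selection(ds2, cfg)
  expect_equal(permuted$frequency[names(base$frequency)], base$frequency,
               tolerance = 1e-12)
})
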