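test_that("a single column equal to the class codes is fit exactly in 1 LV", {
  y <- c(1, 1, -1, -1, 1, -1)
  x <- matrix(y, ncol = 1)
  m <- fit_pls(x, y, n_lv = 1)
  expect_equal(predict(m, x), y, tolerance = 1e-10)
})

test_that("NIPALS matches an independently coded textbook oracle", {
  set.seed(42)
  for (rep in 1:5) {
    x <- autoscale(matrix(rnorm(200), 20, 10))$x
    y <- rep(c(1, -1), 10)
    for (a in 1:3) {
      m <- fit_pls(x, y, n_lv = a)
      o <- oracle_nipals(x, y, a)
      expect_equal(m$b, o$b, tolerance = 1e-6,
                   ignore_attr = TRUE)
    }
  }
})

test_that("at the full component count PLS equals least squares", {
  set.seed(43)
  x <- autoscale(matrix(rnorm(96), 12, 8))$x
  y <- rep(c(1, -1), 6)
  m <- fit_pls(x, y, n_lv = 8)
  ls_fit <- lm.fit(cbind(1, x), y)
  expect_equal(unname(predict(m, x)),
               unname(cbind(1, x) %*% ls_fit$coefficients)[, 1],
               tolerance = 1e-6)
})

test_that("training diagnostics behave as the theory requires", {
  set.seed(44)
  x <- autoscale(matrix(rnorm(15 * 8), 15, 8))$x
  y <- rep(c(1, -1), length.out = 15)
  m <- fit_pls(x, y, n_lv = 5)
  # score vectors pairwise orthogonal
  Tm <- x %*% m$W %*% solve(crossprod(m$P, m$W))
  g <- crossprod(Tm)
  expect_lt(max(abs(g[upper.tri(g)])) / max(diag(g)), 1e-8)
  # explained y-variance non-decreasing in the component count
  rss <- vapply(1:5, function(a) {
    b_a <- plsvip:::.pls_coef(m$W, m$P, m$q, a)
    sum((drop(x %*% b_a) + m$y_mean - y)^2)
  }, numeric(1))
  expect_true(all(diff(rss) < 1e-10))
})

test_that("rank exhaustion is reported when y is orthogonal to X", {
  y <- c(1, -1, 1, -1)
  x <- cbind(c(1, 1, -1, -1), c(1, -1, -1, 1))
  expect_error(fit_pls(x, y, n_lv = 1),
               regexp = "component 1",
               class = "plsvip_rank_exhausted_error")
})

test_that("venetian blind folds interleave samples", {
  expect_equal(venetian_blind_folds(8, 4), rep(1:4, 2))
  f9 <- venetian_blind_folds(9, 4)
  expect_equal(as.vector(table(f9)), c(3, 2, 2, 2))
  expect_error(venetian_blind_folds(3, 4),
               class = "plsvip_infeasible_fold_error")
})

test_that("the RMSECV curve picks one latent variable for a one-factor
           problem and is minimal at the choice", {
  set.seed(45)
  y <- rep(c(1, -1), 12)
  # one latent factor drives every column; extra components only overfit
  x <- outer(y, rep(1, 10)) + matrix(rnorm(240, 0, 0.2), 24, 10)
  curve <- rmsecv_curve(x, y, a_max = 6, k = 4)
  expect_equal(curve$n_lv, 1L)
  expect_true(all(curve$rmsecv >= 0) && all(is.finite(curve$rmsecv)))
  # chosen count is the smallest index attaining the minimum (tie rule)
  expect_equal(curve$n_lv,
               min(which(curve$rmsecv == min(curve$rmsecv))))
})

test_that("duplicated columns exhaust the rank gracefully inside the curve", {
  set.seed(46)
  base <- rnorm(16)
  y <- rep(c(1, -1), 8)
  x <- cbind(base, base)
  curve <- rmsecv_curve(x, y, a_max = 2, k = 4)
  # only one informative direction exists, so only one LV can be scanned
  expect_equal(curve$a_max, 1L)
  expect_equal(curve$n_lv, 1L)
})

test_that("single-class training partitions are refused", {
  x <- matrix(rnorm(40), 10, 4)
  y <- c(rep(1, 9), -1)   # the minority sample sits in exactly one fold
  expect_error(rmsecv_curve(x, y, a_max = 2, k = 4),
               class = "plsvip_stratification_error")
})

test_that("VIP scores obey the formula, its identity, and rank the
           informative feature first", {
  # one feature: normalization forces VIP = 1
  y <- rep(c(1, -1), 4)
  m1 <- fit_pls(autoscale(matrix(y + rnorm(8, 0, 0.1), 8, 1))$x, y, 1)
  expect_equal(unname(vip_scores(m1)), 1, tolerance = 1e-12)

  set.seed(47)
  y <- rep(c(1, -1), 10)
  x <- cbind(y + rnorm(20, 0, 0.3), matrix(rnorm(40), 20, 2))
  colnames(x) <- c("inf", "n1", "n2")
  m <- fit_pls(autoscale(x)$x, y, n_lv = 2)
  vip <- vip_scores(m)
  expect_equal(vip, oracle_vip(m$W, m$ssy), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(names(which.max(vip)), "inf")
  expect_equal(sum(vip^2), 3, tolerance = 1e-8)
})

test_that("classification uses the midpoint rule and counts disagreements", {
  sep <- make_separable(8, 8, J = 10, effect = 6, seed = 48)
  sc <- autoscale(sep$x)
  m <- set_model_scaling(fit_pls(sc$x, sep$y, 1), sc$center, sc$scale)
  res <- classify_samples(m, sep$x, sep$y)
  expect_equal(res$misclassified, 0)
  # inverting the labels gives the complementary count
  inv <- classify_samples(m, sep$x, -sep$y)
  expect_equal(inv$misclassified, length(sep$y) - res$misclassified)
  # a prediction exactly at the midpoint goes to the responder class
  res0 <- classify_samples(m, matrix(m$center, 1, 10))
  expect_equal(unname(res0$yhat), 0, tolerance = 1e-12)
  expect_equal(as.character(res0$class), "responder")
  expect_error(predict(m, sep$x[, 1:5]), class = "plsvip_shape_error")
})
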