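test_that("deviance explained identities and clamping", {
  expect_equal(deviance_explained(100, 100), 0)
  expect_equal(deviance_explained(0, 100), 1)
  expect_equal(deviance_explained(80, 100, percent = TRUE), 20)
  expect_warning(de <- deviance_explained(110, 100), "clamping")
  expect_equal(de, 0)
})

test_that("AUC: identities, worked example, tie handling, symmetry", {
  # perfect separation
  expect_equal(auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  # constant scores: every pair is a tie
  expect_equal(auc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  # worked 4-point example: 3 of 4 pairs concordant
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(auc(1:5, rep(1, 5)), "single-class")

  # auc(s) + auc(-s) = 1 for tie-free scores
  set.seed(41)
  s <- rnorm(60); l <- rbinom(60, 1, 0.5)
  expect_equal(auc(s, l) + auc(-s, l), 1)

  # agrees with the reference ROC implementation, ties included
  skip_if_not_installed("pROC")
  s2 <- sample(seq(0, 1, by = 0.1), 100, replace = TRUE)
  l2 <- rbinom(100, 1, 0.4)
  ref <- as.numeric(pROC::auc(pROC::roc(l2, s2, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc(s2, l2), ref, tolerance = 1e-12)
})

test_that("cross-validation: oracle, constant scores, reproducibility", {
  set.seed(42)
  n <- 400
  X <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "x1"))
  p_true <- plogis(6 * X[, 1])  # nearly separable truth
  y <- rbinom(n, 1, p_true)

  oracle_factory <- function(X_tr, y_tr, pts) {
    function(X_te, pts_te) plogis(6 * X_te[, 1])
  }
  cv <- cross_validate(oracle_factory, X, y, n_repeats = 20, seed = 7)
  expect_gt(cv$mean_auc, 0.9)

  const_factory <- function(X_tr, y_tr, pts) {
    function(X_te, pts_te) rep(0.5, nrow(X_te))
  }
  cv0 <- cross_validate(const_factory, X, y, n_repeats = 10, seed = 7)
  expect_true(all(cv0$per_repeat_auc == 0.5))

  cv_a <- cross_validate(oracle_factory, X, y, n_repeats = 15, seed = 9)
  cv_b <- cross_validate(oracle_factory, X, y, n_repeats = 15, seed = 9)
  expect_identical(cv_a$per_repeat_auc, cv_b$per_repeat_auc)
  expect_equal(length(cv_a$per_repeat_auc), 15)
  expect_equal(cv_a$mean_auc, mean(cv_a$per_repeat_auc))
  expect_equal(cv_a$sd_auc, sd(cv_a$per_repeat_auc))
})

test_that("GWR cross-validation factory transfers nearest-location
           coefficients without using test labels", {
  ds <- synthetic_preset("nonstationary", n_points = 250, seed = 43)
  cv <- cross_validate(gwr_cv_factory(kernel_spec(100)), ds$X, ds$y,
                       ds$points, n_repeats = 3, seed = 11)
  expect_true(all(cv$per_repeat_auc > 0.5))
})

test_that("Moran's I: expectation, checkerboard, gradient, oracle", {
  # closed-form null expectation
  pts <- data.frame(x = rnorm(10) * 100, y = rnorm(10) * 100)
  m <- morans_i(rnorm(10), pts, k = 3, n_permutations = 99)
  expect_equal(m$expected_i, -1 / 9)

  # alternating +-1 on a line with 1 nearest neighbour: perfect dispersion
  line <- data.frame(x = as.numeric(1:20), y = 0)
  chk <- rep(c(1, -1), 10)
  m2 <- morans_i(chk, line, k = 1, n_permutations = 99)
  expect_equal(m2$statistic_i, -1, tolerance = 1e-12)

  # smooth gradient on a grid: strong positive autocorrelation
  g <- make_grid_points(15, 15, spacing = 1000)
  vals <- g$x / 1000 + g$y / 2000
  m3 <- morans_i(vals, g, k = 8, n_permutations = 999, seed = 5)
  expect_gt(m3$statistic_i, 0.5)
  expect_lte(m3$p_value, 0.002)

  expect_error(morans_i(rep(1, 20), make_grid_points(5, 4)), "constant")

  # statistic matches the reference implementation on the same W
  skip_if_not_installed("ape")
  set.seed(6)
  pts2 <- data.frame(x = runif(30) * 1e4, y = runif(30) * 1e4)
  v <- rnorm(30)
  m4 <- morans_i(v, pts2, k = 5, n_permutations = 9)
  W <- matrix(0, 30, 30)
  P <- as.matrix(pts2)
  for (i in 1:30) {
    d2 <- (P[, 1] - P[i, 1])^2 + (P[, 2] - P[i, 2])^2; d2[i] <- Inf
    W[i, order(d2)[1:5]] <- 1 / 5
  }
  ref <- ape::Moran.I(v, W, scaled = FALSE)
  expect_equal(m4$statistic_i, ref$observed, tolerance = 1e-10)
})

test_that("Moran permutation p-value follows its defining formula", {
  set.seed(8)
  pts <- data.frame(x = runif(40) * 1e4, y = runif(40) * 1e4)
  v <- rnorm(40)
  m <- morans_i(v, pts, k = 6, n_permutations = 199, seed = 3)
  expect_equal(m$p_value,
               (1 + sum(abs(m$permuted) >= abs(m$statistic_i))) / 200)
  expect_gt(m$p_value, 0)
  expect_lte(m$p_value, 1)
})

test_that("residuals_by_year: summaries, null calibration, shift detection", {
  set.seed(9)
  years <- rep(2000:2009, each = 20)
  res <- rnorm(200)
  out <- residuals_by_year(res, years)
  expect_equal(nrow(out$table), 10)
  expect_equal(sum(out$table$mean * out$table$n) / sum(out$table$n),
               mean(res), tolerance = 1e-12)

  # one year shifted by 2 SD is flagged
  res2 <- res; res2[years == 2004] <- res2[years == 2004] + 2
  expect_lt(residuals_by_year(res2, years)$anova_p, 0.001)

  # years with one observation are excluded with a warning
  expect_warning(out3 <- residuals_by_year(c(res, 5), c(years, 2019)),
                 "2019")
  expect_true(is.finite(out3$anova_p))

  # under a common distribution the ANOVA p-value is uniform
  ps <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    residuals_by_year(rnorm(120), rep(2001:2006, each = 20))$anova_p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.05)
})
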