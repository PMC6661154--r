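test_that("Gaussian kernel weight identities", {
  expect_equal(kernel_weights(0, 5), 1)
  expect_equal(kernel_weights(sqrt(5), 5), exp(-1))
  d <- seq(0, 100, by = 1)
  w <- kernel_weights(d, 50)
  expect_true(all(diff(w) < 0))
  expect_lt(kernel_weights(1e6, 1), 1e-300)
  # half-exponent convention
  expect_equal(kernel_weights(sqrt(10), 5, half = TRUE), exp(-1))
  expect_error(kernel_weights(1, -1), "positive")
})

test_that("adaptive scale counts neighbours correctly, duplicates included", {
  pts <- data.frame(x = c(0, 1, 2), y = 0)
  expect_equal(adaptive_scale(pts, 1, 2), 4)  # 2nd neighbour of x=0 is x=2
  expect_equal(adaptive_scale(pts, 2, 1), 1)

  # corner of a regular 10x10 unit grid: third-nearest is the diagonal
  g <- make_grid_points(10, 10)
  expect_equal(adaptive_scale(g, 1, 3), 2)

  # duplicated coordinates count as neighbours at distance zero
  dup <- data.frame(x = c(0, 0, 5), y = 0)
  expect_equal(adaptive_scale(dup, 1, 1), 0)
  expect_equal(adaptive_scale(dup, 1, 2), 25)
  expect_error(adaptive_scale(pts, 1, 10), "N")
})

test_that("local weighted fit equals the global fit under equal weights and
           matches a brute-force weighted maximizer", {
  fx <- make_logistic_fixture(n = 80, p = 2, seed = 11)
  glob <- fit_global_logistic(fx$X, fx$y)
  loc <- fit_local_logistic(fx$X, fx$y, rep(1, 80))
  expect_equal(unname(loc$coefficients), unname(glob$coefficients),
               tolerance = 1e-8)

  set.seed(12)
  w <- runif(80, 0.05, 1)
  loc_w <- fit_local_logistic(fx$X, fx$y, w)
  expect_equal(unname(loc_w$coefficients), optim_logistic(fx$X, fx$y, w),
               tolerance = 1e-6)

  # one-hot weights: effectively a single observation, unestimable
  w1 <- c(1, rep(0, 79))
  expect_false(fit_local_logistic(fx$X, fx$y, w1)$estimable)
})

test_that("GWR at enormous bandwidth reproduces the global logistic fit", {
  fx <- make_logistic_fixture(n = 120, p = 2, seed = 13)
  glob <- fit_global_logistic(fx$X, fx$y)
  dmax <- max(dist(fx$points))
  fit <- fit_gwr(fx$X, fx$y, fx$points,
                 kernel_spec(1e6 * dmax, adaptive = FALSE))
  for (j in seq_len(3)) {
    expect_lt(max(abs(fit$local_coefficients[, j] - glob$coefficients[j])),
              1e-4)
  }
  expect_equal(gwr_aic(fit), glob$aic, tolerance = 0.1)
  # effective parameters collapse to p + 1 in the global limit
  expect_equal(fit$effective_parameters, 3, tolerance = 1e-3)
})

test_that("GWR structure invariants: t-values, hat trace, probability range", {
  ds <- synthetic_preset("nonstationary", n_points = 300, seed = 21)
  fit <- fit_gwr(ds$X, ds$y, ds$points, kernel_spec(80))
  expect_equal(fit$local_t_values,
               fit$local_coefficients / fit$local_standard_errors)
  expect_equal(fit$effective_parameters, sum(fit$hat_diagonal))
  expect_true(all(fit$fitted_probabilities > 0 &
                    fit$fitted_probabilities < 1))
  expect_true(all(fit$hat_diagonal > 0 & fit$hat_diagonal <= 1 + 1e-9))
  expect_gte(fit$effective_parameters, ncol(ds$X) + 1)
  expect_lte(fit$effective_parameters, nrow(ds$X))

  # effective parameters shrink as the bandwidth grows
  fit_wide <- fit_gwr(ds$X, ds$y, ds$points, kernel_spec(250))
  expect_lt(fit_wide$effective_parameters, fit$effective_parameters)

  # AIC formula
  expect_equal(fit$aic, fit$deviance + 2 * fit$effective_parameters)
})

test_that("permuting sample order permutes GWR outputs identically", {
  ds <- synthetic_preset("nonstationary", n_points = 150, seed = 22)
  fit <- fit_gwr(ds$X, ds$y, ds$points, kernel_spec(60))
  set.seed(23)
  perm <- sample.int(150)
  fit_p <- fit_gwr(ds$X[perm, ], ds$y[perm], ds$points[perm, ],
                   kernel_spec(60))
  expect_equal(fit_p$local_coefficients, fit$local_coefficients[perm, ],
               tolerance = 1e-9)
  expect_equal(fit_p$fitted_probabilities, fit$fitted_probabilities[perm],
               tolerance = 1e-9)
  expect_equal(fit_p$aic, fit$aic, tolerance = 1e-7)
})

test_that("stationarity index formula and degenerate cases", {
  ds <- synthetic_preset("nonstationary", n_points = 200, seed = 24)
  glob <- fit_global_logistic(ds$X, ds$y)
  fit <- fit_gwr(ds$X, ds$y, ds$points, kernel_spec(70))
  tab <- stationarity_index(fit, glob)
  # five-number summaries are ordered
  expect_true(all(tab$minimum <= tab$lower_quartile))
  expect_true(all(tab$lower_quartile <= tab$median))
  expect_true(all(tab$median <= tab$upper_quartile))
  expect_true(all(tab$upper_quartile <= tab$maximum))
  # formula check against direct computation
  j <- which(tab$variable == "temperature")
  iqr <- diff(quantile(fit$local_coefficients[, "temperature"],
                       c(0.25, 0.75)))
  expect_equal(tab$si[j],
               unname(iqr / (2 * glob$standard_errors["temperature"])))

  # constant local coefficients -> SI exactly 0
  fake <- fit
  fake$local_coefficients[] <- rep(colMeans(fit$local_coefficients),
                                   each = nrow(fit$local_coefficients))
  expect_equal(stationarity_index(fake, glob)$si, rep(0, 5))
})

test_that("local significance mask follows the two-sided normal test", {
  ds <- synthetic_preset("nonstationary", n_points = 150, seed = 25)
  fit <- fit_gwr(ds$X, ds$y, ds$points, kernel_spec(60))
  mask <- local_significance(fit)
  expect_equal(dim(mask), dim(fit$local_t_values))
  # t = 0 is never significant; |t| = 1.96 sits just under the boundary
  fit$local_t_values[1, 1] <- 0
  fit$local_t_values[1, 2] <- qnorm(0.975)  # exactly p = 0.05
  fit$local_t_values[1, 3] <- 2.00
  m <- local_significance(fit)
  expect_false(m[1, 1])
  expect_false(m[1, 2])  # p = 0.05 is not strictly < 0.05
  expect_true(m[1, 3])
})

test_that("bandwidth selection tracks the nonstationarity of the truth", {
  # strongly nonstationary truth -> narrow bandwidth (bottom half of range)
  ds <- synthetic_preset("nonstationary", n_points = 400, seed = 26)
  sel <- select_bandwidth(ds$X, ds$y, ds$points)
  expect_lt(sel$N, 200)
  expect_true(all(diff(sel$trace$N) > 0))
  expect_true(is.finite(min(sel$trace$aic)))

  # stationary truth -> wide bandwidth (top quartile)
  ds0 <- stationary_null(n_points = 400, seed = 27)
  sel0 <- select_bandwidth(ds0$X, ds0$y, ds0$points)
  expect_gt(sel0$N, 300)
})
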