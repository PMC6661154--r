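#' Fraction of null deviance explained
#'
#' `(null - fit) / null`, the GLM analogue of R-squared. A fitted
#' deviance above the null deviance (a misconverged fit) is clamped to
#' zero with a warning.
#'
#' @param fit_deviance deviance of the fitted model.
#' @param null_deviance deviance of the intercept-only model (> 0).
#' @param percent return a percentage instead of a fraction.
#' @export
deviance_explained <- function(fit_deviance, null_deviance, percent = FALSE) {
  stopifnot(null_deviance > 0)
  de <- (null_deviance - fit_deviance) / null_deviance
  if (de < 0) {
    warning("fitted deviance exceeds null deviance; clamping to 0")
    de <- 0
  }
  if (percent) 100 * de else de
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' presence scores above a randomly chosen absence, counting ties as one
#' half. Equals the trapezoidal area under the ROC curve.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (both classes required).
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: single-class labels")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated random-split cross-validation of a presence model
#'
#' Splits the data at random into training and testing parts (default
#' ratio 3:1), fits the model on the training part and scores the test
#' part with AUC, repeating `n_repeats` times. A repeat whose test fold
#' contains a single class is redrawn (and counted). Fully reproducible
#' from `seed`.
#'
#' @param model_factory function `(X_train, y_train, points_train)`
#'   returning a prediction function `(X_test, points_test) -> scores`.
#'   See [gwr_cv_factory()], [global_cv_factory()], [gam_cv_factory()].
#' @param X,y covariates and binary response.
#' @param points projected coordinates (may be NULL for aspatial models).
#' @param n_repeats number of random splits (default 100).
#' @param train_fraction fraction of rows used for training (default 0.75).
#' @param seed RNG seed.
#' @return object of class `cv_result` with `per_repeat_auc`, `mean_auc`,
#'   `sd_auc`, `ci95` (percentile interval), `n_redraws`.
#' @export
cross_validate <- function(model_factory, X, y, points = NULL,
                           n_repeats = 100L, train_fraction = 0.75,
                           seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  n_train <- round(train_fraction * n)
  set.seed(seed)
  aucs <- numeric(n_repeats)
  redraws <- 0L
  for (r in seq_len(n_repeats)) {
    repeat {
      idx <- sample.int(n, n_train)
      y_te <- y[-idx]
      if (length(unique(y_te)) == 2L) break
      redraws <- redraws + 1L
    }
    pts_tr <- if (is.null(points)) NULL else points[idx, , drop = FALSE]
    pts_te <- if (is.null(points)) NULL else points[-idx, , drop = FALSE]
    predictor <- model_factory(X[idx, , drop = FALSE], y[idx], pts_tr)
    scores <- predictor(X[-idx, , drop = FALSE], pts_te)
    aucs[r] <- auc(scores, y_te)
  }
  structure(list(n_repeats = n_repeats, train_fraction = train_fraction,
                 per_repeat_auc = aucs, mean_auc = mean(aucs),
                 sd_auc = stats::sd(aucs),
                 ci95 = unname(stats::quantile(aucs, c(0.025, 0.975))),
                 n_redraws = redraws),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-repeat %.0f:%.0f cross-validation: mean AUC %.3f +/- %.3f (95%% CI %.3f-%.3f)\n",
              x$n_repeats, 100 * x$train_fraction,
              100 * (1 - x$train_fraction),
              x$mean_auc, x$sd_auc, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Cross-validation factory for the geographically weighted model
#'
#' Refits the GWR at the training locations with the supplied kernel;
#' each test point is scored with the local coefficient vector of its
#' nearest training location (no test labels are used in fitting).
#'
#' @param kernel a [kernel_spec()].
#' @return a model factory for [cross_validate()].
#' @export
gwr_cv_factory <- function(kernel) {
  function(X_tr, y_tr, pts_tr) {
    k <- kernel
    if (k$adaptive) k$bandwidth <- min(k$bandwidth, nrow(X_tr) - 1L)
    fit <- fit_gwr(X_tr, y_tr, pts_tr, k)
    B <- fit$local_coefficients
    P_tr <- as.matrix(pts_tr[, c("x", "y")])
    function(X_te, pts_te) {
      P_te <- as.matrix(pts_te[, c("x", "y")])
      nn <- nearest_index(P_te, P_tr)
      eta <- rowSums(cbind(1, as.matrix(X_te)) * B[nn, , drop = FALSE])
      stats::plogis(eta)
    }
  }
}

#' @rdname gwr_cv_factory
#' @export
global_cv_factory <- function() {
  function(X_tr, y_tr, pts_tr) {
    fit <- fit_global_logistic(X_tr, y_tr)
    function(X_te, pts_te) predict_probability(fit, X_te)
  }
}

#' @rdname gwr_cv_factory
#' @param basis_dim,gamma passed to [fit_gam()].
#' @export
gam_cv_factory <- function(basis_dim = 10, gamma = 1.4) {
  function(X_tr, y_tr, pts_tr) {
    fit <- fit_gam(X_tr, y_tr, basis_dim = basis_dim, gamma = gamma)
    function(X_te, pts_te)
      suppressWarnings(predict_probability(fit, X_te))
  }
}

# index of the nearest row of `ref` for every row of `query` (small m x n)
nearest_index <- function(query, ref) {
  vapply(seq_len(nrow(query)), function(i) {
    which.min((ref[, 1] - query[i, 1])^2 + (ref[, 2] - query[i, 2])^2)
  }, integer(1))
}

#' Moran's I with a permutation test
#'
#' Spatial autocorrelation of `values` on a k-nearest-neighbour graph
#' (binary weights, row-standardized):
#' `I = (n / S0) * (z' W z) / (z' z)` with `z` the centred values and
#' `S0` the sum of all weights. Significance is assessed by a two-sided
#' permutation test:
#' `p = (1 + #\{|I_perm| >= |I_obs|\}) / (1 + n_permutations)`.
#'
#' @param values numeric vector (non-constant, n >= 10).
#' @param points projected coordinates with columns `x`, `y`.
#' @param k number of nearest neighbours in the weight graph (default 8).
#' @param n_permutations number of random relabellings (default 999).
#' @param seed RNG seed for the permutations.
#' @return object of class `moran_result` with `statistic_i`,
#'   `expected_i`, `p_value`, `n_permutations`.
#' @export
morans_i <- function(values, points, k = 8L, n_permutations = 999L,
                     seed = 1L) {
  n <- length(values)
  stopifnot(nrow(points) == n)
  if (n < 10L) stop("need at least 10 observations")
  if (stats::sd(values) == 0) stop("constant values: Moran's I undefined")

  P <- as.matrix(points[, c("x", "y")])
  # neighbour edge list: i -> its k nearest other points, weight 1/k
  nb <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d2 <- (P[, 1] - P[i, 1])^2 + (P[, 2] - P[i, 2])^2
    d2[i] <- Inf
    nb[i, ] <- order(d2)[seq_len(k)]
  }
  ei <- rep(seq_len(n), each = k)
  ej <- as.vector(t(nb))
  wt <- rep(1 / k, length(ei))
  S0 <- sum(wt)

  moran_stat <- function(z) {
    (n / S0) * sum(wt * z[ei] * z[ej]) / sum(z * z)
  }
  z <- values - mean(values)
  i_obs <- moran_stat(z)

  set.seed(seed)
  i_perm <- vapply(seq_len(n_permutations), function(b) {
    moran_stat(z[sample.int(n)])
  }, numeric(1))
  p <- (1 + sum(abs(i_perm) >= abs(i_obs))) / (1 + n_permutations)

  structure(list(statistic_i = i_obs, expected_i = -1 / (n - 1),
                 n_permutations = n_permutations, p_value = p,
                 permuted = i_perm),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f), permutation p = %.4f (%d permutations)\n",
              x$statistic_i, x$expected_i, x$p_value, x$n_permutations))
  invisible(x)
}

#' Residuals summarized by survey year
#'
#' Per-year mean, SD and count of model residuals, with a one-way ANOVA
#' F-test for differences in mean residual among years — the check for
#' temporal structure left unmodelled when multi-year data are pooled
#' into one spatial fit. Years with a single observation are excluded
#' from the ANOVA with a warning.
#'
#' @param residuals numeric residual vector.
#' @param years integer calendar years, same length.
#' @return object of class `year_residuals` with `table` (year, mean, sd,
#'   n), `anova_statistic`, `anova_p`.
#' @export
residuals_by_year <- function(residuals, years) {
  stopifnot(length(residuals) == length(years))
  yr <- as.integer(years)
  if (length(unique(yr)) < 2L) stop("need at least two years")
  tab <- do.call(rbind, lapply(split(residuals, yr), function(v) {
    data.frame(mean = mean(v), sd = stats::sd(v), n = length(v))
  }))
  tab <- cbind(year = as.integer(rownames(tab)), tab)
  rownames(tab) <- NULL

  singletons <- tab$year[tab$n < 2L]
  if (length(singletons)) {
    warning("year(s) with a single observation excluded from ANOVA: ",
            paste(singletons, collapse = ", "))
  }
  keep <- !(yr %in% singletons)
  fit <- stats::aov(residuals[keep] ~ factor(yr[keep]))
  an <- summary(fit)[[1]]
  structure(list(table = tab,
                 anova_statistic = an[["F value"]][1],
                 anova_p = an[["Pr(>F)"]][1]),
            class = "year_residuals")
}

#' @export
print.year_residuals <- function(x, ...) {
  print(x$table, digits = 3)
  cat(sprintf("one-way ANOVA across years: F = %.2f, p = %.4g\n",
              x$anova_statistic, x$anova_p))
  invisible(x)
}
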