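#' Global logistic regression
#'
#' Maximum-likelihood logistic fit of presence/absence on the
#' environmental covariates, by iteratively reweighted least squares.
#' Standard errors come from the inverse observed Fisher information.
#' This is the stationary reference model: its standard errors form the
#' denominator of the stationarity index, and it is the limit of the
#' geographically weighted fit as the bandwidth grows without bound.
#' Complete separation triggers a tiny L2 ridge (1e-6) on the slopes and
#' a `ridged` flag rather than failure.
#'
#' @param X n x p numeric covariate matrix or data.frame.
#' @param y binary response (both classes must be present).
#' @return object of class `global_logistic_fit` with elements
#'   `coefficients`, `standard_errors`, `vcov`, `fitted_probabilities`,
#'   `deviance`, `null_deviance`, `aic`, `deviance_explained`, `ridged`.
#' @export
fit_global_logistic <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  stopifnot(length(y) == n, n > p + 1)
  if (length(unique(y)) < 2L) stop("response contains a single class")
  Z <- cbind(`(Intercept)` = 1, X)
  fit <- irls_logistic(Z, y)
  if (!isTRUE(fit$estimable)) stop("global logistic fit failed")
  null_dev <- binomial_deviance(y, rep(mean(y), n))
  structure(list(
    coefficients = stats::setNames(fit$coefficients, colnames(Z)),
    standard_errors = stats::setNames(fit$standard_errors, colnames(Z)),
    vcov = fit$vcov,
    fitted_probabilities = fit$fitted,
    deviance = fit$deviance,
    null_deviance = null_dev,
    aic = fit$deviance + 2 * (p + 1),
    deviance_explained = (null_dev - fit$deviance) / null_dev,
    ridged = fit$ridged,
    y = y, X = X
  ), class = "global_logistic_fit")
}

#' @export
print.global_logistic_fit <- function(x, ...) {
  cat("Global logistic regression\n")
  print(data.frame(estimate = x$coefficients, se = x$standard_errors,
                   z = x$coefficients / x$standard_errors))
  cat(sprintf("deviance %.1f (null %.1f), AIC %.1f, deviance explained %.1f%%\n",
              x$deviance, x$null_deviance, x$aic,
              100 * x$deviance_explained))
  invisible(x)
}

#' Penalized-spline additive logistic model
#'
#' Binomial additive model with one penalized cubic regression spline per
#' covariate, fitted with `mgcv::gam`. Smoothness is selected
#' automatically with the effective degrees of freedom inflated by
#' `gamma` (default 1.4) to guard against overfitting. Per-term
#' chi-square statistics and p-values, effective df, AIC and deviance
#' explained are extracted into a light summary object alongside the
#' underlying mgcv fit.
#'
#' @param X n x p covariate matrix or data.frame.
#' @param y binary response.
#' @param basis_dim spline basis dimension per term (default 10); reduced
#'   with a warning for covariates with too few distinct values.
#' @param gamma effective-df inflation in the smoothness criterion.
#' @return object of class `gam_fit`.
#' @export
fit_gam <- function(X, y, basis_dim = 10, gamma = 1.4) {
  X <- as.data.frame(X)
  if (is.null(names(X))) names(X) <- paste0("x", seq_along(X))
  stopifnot(length(y) == nrow(X))
  if (length(unique(y)) < 2L) stop("response contains a single class")

  k_use <- vapply(X, function(v) {
    nu <- length(unique(v))
    min(basis_dim, nu - 1L)
  }, numeric(1))
  if (any(k_use < basis_dim))
    warning("basis dimension reduced for: ",
            paste(names(X)[k_use < basis_dim], collapse = ", "))
  if (any(k_use < 3)) stop("covariate(s) with too few distinct values")

  terms <- sprintf('s(%s, k = %d, bs = "cr")', names(X), k_use)
  fml <- stats::as.formula(paste(".presence ~", paste(terms, collapse = " + ")))
  dat <- cbind(.presence = y, X)
  g <- mgcv::gam(fml, family = stats::binomial(), data = dat, gamma = gamma)
  sm <- summary(g)

  structure(list(
    smooth_terms = data.frame(
      term = names(X),
      basis_dim = k_use,
      edf = as.numeric(sm$edf),
      chi_sq = as.numeric(sm$chi.sq),
      p_value = as.numeric(sm$s.pv),
      stringsAsFactors = FALSE),
    linear_predictor = as.numeric(g$linear.predictors),
    fitted_probabilities = as.numeric(g$fitted.values),
    deviance = g$deviance,
    null_deviance = g$null.deviance,
    deviance_explained = sm$dev.expl,
    aic = stats::AIC(g),
    gcv_ubre = as.numeric(g$gcv.ubre),
    mgcv_fit = g,
    y = y
  ), class = "gam_fit")
}

#' @export
print.gam_fit <- function(x, ...) {
  cat("Binomial additive model (penalized cubic regression splines)\n")
  print(x$smooth_terms, digits = 3)
  cat(sprintf("AIC %.1f, deviance explained %.1f%%\n",
              x$aic, 100 * x$deviance_explained))
  invisible(x)
}

#' Predict presence probability from a fitted baseline model
#'
#' Inverse-logit of the linear predictor at new covariate values. For the
#' additive model, covariates outside the training span trigger an
#' extrapolation warning but a value is still returned.
#'
#' @param fit a `global_logistic_fit` or `gam_fit`.
#' @param X_new m x p matrix/data.frame with the training covariates.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_probability <- function(fit, X_new) {
  UseMethod("predict_probability")
}

#' @export
predict_probability.global_logistic_fit <- function(fit, X_new) {
  X_new <- as.matrix(X_new)
  stopifnot(ncol(X_new) == length(fit$coefficients) - 1L)
  drop(stats::plogis(cbind(1, X_new) %*% fit$coefficients))
}

#' @export
predict_probability.gam_fit <- function(fit, X_new) {
  X_new <- as.data.frame(X_new)
  tr <- fit$mgcv_fit$model
  for (v in fit$smooth_terms$term) {
    rng <- range(tr[[v]])
    if (any(X_new[[v]] < rng[1] | X_new[[v]] > rng[2])) {
      warning("extrapolating beyond the training range of ", v)
      break
    }
  }
  as.numeric(stats::predict(fit$mgcv_fit, newdata = X_new, type = "response"))
}
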