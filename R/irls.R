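# Weighted-likelihood logistic IRLS engine shared by the global fit and
# the kernel-weighted local fits. Maximizes sum_i w_i * loglik_i(beta).
# On (weighted) separation the normal equations are re-solved with a tiny
# L2 ridge on the slope coefficients and the fit is flagged, so that local
# fits on small effective samples degrade gracefully instead of diverging.
#
# Z is the design matrix INCLUDING the intercept column.
irls_logistic <- function(Z, y, w = rep(1, length(y)), start = NULL,
                          ridge = 1e-6, tol = 1e-8, max_iter = 100L) {
  n <- nrow(Z); q <- ncol(Z)
  pen0 <- diag(c(0, rep(1, q - 1L)), q)  # ridge never touches the intercept

  run <- function(lambda) {
    beta <- if (is.null(start)) numeric(q) else start
    dev_old <- Inf; dev <- Inf
    ok <- TRUE
    for (it in seq_len(max_iter)) {
      eta <- drop(Z %*% beta)
      mu <- stats::plogis(eta)
      mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
      v <- mu * (1 - mu)
      ww <- w * v
      z_work <- eta + (y - mu) / v
      XtW <- t(Z * ww)
      A <- XtW %*% Z + lambda * pen0
      beta_new <- tryCatch(solve(A, XtW %*% z_work),
                           error = function(e) NULL)
      if (is.null(beta_new) || any(!is.finite(beta_new))) { ok <- FALSE; break }
      beta <- drop(beta_new)
      dev <- -2 * sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
      if (is.finite(dev_old) && abs(dev_old - dev) < tol) break
      dev_old <- dev
    }
    # an exit with extreme linear predictors is the separation signature
    # (the unpenalized MLE is off at infinity); deviance convergence alone
    # does not rule it out
    sep <- ok && lambda == 0 && max(abs(drop(Z %*% beta))) > 30
    diverged <- !ok || !is.finite(dev) || any(abs(beta) > 1e6) || sep
    list(beta = beta, dev = dev, ok = ok, diverged = diverged,
         iters = it, mu = if (ok) mu else NULL)
  }

  fit <- run(0)
  ridged <- FALSE
  if (fit$diverged) {
    fit <- run(ridge)
    ridged <- TRUE
    if (fit$diverged) return(list(estimable = FALSE, ridged = TRUE))
  }

  beta <- fit$beta
  eta <- drop(Z %*% beta)
  mu <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
  v <- mu * (1 - mu)
  ww <- w * v
  A <- t(Z * ww) %*% Z + (if (ridged) ridge else 0) * pen0
  info_inv <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(info_inv)) return(list(estimable = FALSE, ridged = ridged))
  se <- sqrt(pmax(diag(info_inv), 0))
  list(estimable = TRUE, coefficients = beta, standard_errors = se,
       vcov = info_inv, fitted = mu, deviance = fit$dev,
       working_weights = ww, ridged = ridged, iterations = fit$iters)
}

binomial_deviance <- function(y, mu) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
}
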