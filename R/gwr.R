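#' Gaussian kernel weights
#'
#' Distance-decay weights `w = exp(-d^2 / h)`, where `h` is a
#' squared-distance scale (for an adaptive kernel, the squared distance to
#' the N-th nearest neighbour; see [adaptive_scale()]). With
#' `half = TRUE` the decay follows the alternative convention
#' `exp(-d^2 / (2 h))` used by some GWR software.
#'
#' @param d numeric vector of non-negative distances (metres).
#' @param h positive squared-distance scale (m^2).
#' @param half logical; use the half-exponent convention.
#' @return weights in (0, 1]; `w(0) = 1`, strictly decreasing in `d`.
#' @export
kernel_weights <- function(d, h, half = FALSE) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("bandwidth scale h must be a positive number")
  if (any(d < 0)) stop("distances must be non-negative")
  exp(-d^2 / (if (half) 2 * h else h))
}

#' Adaptive kernel scale at one regression point
#'
#' For an adaptive bandwidth of N neighbours, the kernel scale at point i
#' is the squared distance from i to its N-th nearest *other* point, so
#' dense areas get narrow kernels and sparse areas wide ones. Duplicated
#' coordinates count as neighbours at distance zero; only point i itself
#' is excluded.
#'
#' @param points data.frame or matrix with columns `x`, `y` (metres).
#' @param i index of the regression point.
#' @param N neighbour count, `1 <= N <= n`.
#' @return squared distance scale `h_i` (m^2).
#' @export
adaptive_scale <- function(points, i, N) {
  P <- as.matrix(points[, c("x", "y")])
  n <- nrow(P)
  if (N < 1 || N > n) stop("neighbour count N must be in [1, n]")
  d <- sqrt((P[, 1] - P[i, 1])^2 + (P[, 2] - P[i, 2])^2)
  d <- sort(d[-i])
  d[min(N, length(d))]^2
}

#' Adaptive or fixed kernel specification
#'
#' @param bandwidth adaptive: integer neighbour count N; fixed: distance
#'   scale in metres (the kernel scale is its square).
#' @param adaptive logical (default TRUE).
#' @param half use the half-exponent Gaussian convention (default FALSE).
#' @return object of class `kernel_spec`.
#' @export
kernel_spec <- function(bandwidth, adaptive = TRUE, half = FALSE) {
  if (bandwidth <= 0) stop("bandwidth must be positive")
  structure(list(family = "gaussian", adaptive = adaptive,
                 bandwidth = if (adaptive) as.integer(round(bandwidth))
                             else bandwidth,
                 half = half),
            class = "kernel_spec")
}

#' Kernel-weighted local logistic fit
#'
#' Maximizes the weighted binomial likelihood by IRLS. Standard errors
#' come from the inverse weighted Fisher information. Locations where the
#' effective sample is too small (total weight <= p + 1, or one response
#' class carries no weight) are flagged unestimable; weighted separation
#' triggers a small ridge (1e-6) on the slopes and a `ridged` flag.
#'
#' @param X n x p covariate matrix (no intercept column).
#' @param y binary response.
#' @param w non-negative observation weights.
#' @param start optional starting coefficients (intercept first).
#' @return list with `estimable`, and when estimable: `coefficients`,
#'   `standard_errors`, `vcov`, `fitted`, `deviance`, `ridged`.
#' @export
fit_local_logistic <- function(X, y, w, start = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (sum(w) <= p + 1 ||
      sum(w[y == 1]) <= 0 || sum(w[y == 0]) <= 0)
    return(list(estimable = FALSE, ridged = FALSE))
  Z <- cbind(`(Intercept)` = 1, X)
  irls_logistic(Z, y, w, start = start)
}

#' Fit a geographically weighted logistic regression
#'
#' Fits one kernel-weighted logistic model at every sample location,
#' assembling local coefficient, standard-error and t-value matrices, the
#' fitted presence probability of each observation under its own local
#' model, the hat diagonal of the local-fit ensemble, the effective
#' number of parameters (trace of the hat matrix), deviance, AIC/AICc and
#' deviance explained.
#'
#' The hat diagonal uses the converged IRLS linearization: at location i,
#' `h_ii = v_i x_i' (Z' W_i V Z)^{-1} x_i` with `V` the binomial variance
#' weights and the kernel self-weight `w_ii = 1`.
#'
#' @param X n x p covariate matrix.
#' @param y binary response vector.
#' @param points data.frame with projected coordinates `x`, `y` (metres).
#' @param kernel a [kernel_spec()].
#' @param max_unestimable tolerated fraction of unestimable locations
#'   before erroring with a suggestion to enlarge the bandwidth.
#' @return object of class `gwr_fit`.
#' @export
fit_gwr <- function(X, y, points, kernel, max_unestimable = 0.05) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, nrow(points) == n)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (!inherits(kernel, "kernel_spec")) stop("kernel must be a kernel_spec")
  if (kernel$adaptive && (kernel$bandwidth < p + 2 || kernel$bandwidth > n))
    stop("adaptive bandwidth N must lie in [p+2, n]")

  P <- as.matrix(points[, c("x", "y")])
  Z <- cbind(`(Intercept)` = 1, X)
  cn <- colnames(Z)

  # warm starts from the global fit speed every local IRLS up considerably
  glob <- irls_logistic(Z, y)
  start <- if (isTRUE(glob$estimable)) glob$coefficients else NULL

  coefs <- matrix(NA_real_, n, p + 1, dimnames = list(NULL, cn))
  ses <- coefs
  fitted <- rep(NA_real_, n)
  hat <- rep(NA_real_, n)
  unest <- logical(n)
  ridged <- logical(n)
  dev_i <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    d <- sqrt((P[, 1] - P[i, 1])^2 + (P[, 2] - P[i, 2])^2)
    h <- if (kernel$adaptive) {
      ds <- sort(d[-i])
      ds[min(kernel$bandwidth, n - 1L)]^2
    } else kernel$bandwidth^2
    if (h <= 0) h <- 1e-8  # all-duplicate neighbourhood degenerates
    w <- kernel_weights(d, h, half = kernel$half)

    # drop negligible weights for speed; the regression point always stays
    keep <- w > 1e-9
    keep[i] <- TRUE
    fit <- fit_local_logistic(X[keep, , drop = FALSE], y[keep], w[keep],
                              start = start)
    if (!isTRUE(fit$estimable)) { unest[i] <- TRUE; next }
    coefs[i, ] <- fit$coefficients
    ses[i, ] <- fit$standard_errors
    ridged[i] <- fit$ridged
    eta_i <- drop(Z[i, ] %*% fit$coefficients)
    mu_i <- pmin(pmax(stats::plogis(eta_i), 1e-12), 1 - 1e-12)
    fitted[i] <- mu_i
    v_i <- mu_i * (1 - mu_i)
    hat[i] <- v_i * drop(Z[i, ] %*% fit$vcov %*% Z[i, ])
    dev_i[i] <- -2 * (y[i] * log(mu_i) + (1 - y[i]) * log(1 - mu_i))
  }

  if (mean(unest) > max_unestimable)
    stop(sprintf(paste0("%d of %d locations unestimable; ",
                        "consider a larger bandwidth"), sum(unest), n))

  ok <- !unest
  enp <- sum(hat[ok])
  deviance <- sum(dev_i[ok])
  p0 <- mean(y[ok])
  null_dev <- binomial_deviance(y[ok], rep(p0, sum(ok)))
  n_ok <- sum(ok)
  aic <- deviance + 2 * enp
  aicc <- aic + 2 * enp * (enp + 1) / max(n_ok - enp - 1, 1e-8)

  structure(list(
    locations = as.data.frame(P),
    local_coefficients = coefs,
    local_standard_errors = ses,
    local_t_values = coefs / ses,
    fitted_probabilities = fitted,
    hat_diagonal = hat,
    bandwidth = kernel,
    effective_parameters = enp,
    deviance = deviance,
    null_deviance = null_dev,
    aic = aic,
    aicc = aicc,
    deviance_explained = (null_dev - deviance) / null_dev,
    unestimable = unest,
    ridged = ridged,
    y = y,
    X = X
  ), class = "gwr_fit")
}

#' @export
print.gwr_fit <- function(x, ...) {
  bw <- x$bandwidth
  cat("Geographically weighted logistic regression\n")
  cat(sprintf("  n = %d, covariates: %s\n", nrow(x$X),
              paste(colnames(x$X), collapse = ", ")))
  cat(sprintf("  %s bandwidth: %s%s\n",
              if (bw$adaptive) "adaptive" else "fixed",
              format(bw$bandwidth),
              if (bw$adaptive) " neighbours" else " m"))
  cat(sprintf("  effective parameters: %.1f\n", x$effective_parameters))
  cat(sprintf("  deviance: %.1f  AIC: %.1f  AICc: %.1f\n",
              x$deviance, x$aic, x$aicc))
  cat(sprintf("  deviance explained: %.1f%%\n", 100 * x$deviance_explained))
  invisible(x)
}

#' Residuals of a GWR fit
#'
#' @param object a `gwr_fit`.
#' @param type `"deviance"` (default) or `"response"` (y - fitted).
#' @param ... unused.
#' @export
residuals.gwr_fit <- function(object, type = c("deviance", "response"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted_probabilities
  if (type == "response") return(r)
  mu <- pmin(pmax(object$fitted_probabilities, 1e-12), 1 - 1e-12)
  d <- -2 * (object$y * log(mu) + (1 - object$y) * log(1 - mu))
  sign(r) * sqrt(d)
}

#' AIC of a GWR fit
#'
#' `AIC = deviance + 2 * effective_parameters`, with the effective number
#' of parameters the trace of the hat matrix of the local-fit ensemble.
#' The small-sample corrected AICc is available via `type = "aicc"`.
#'
#' @param fit a `gwr_fit`.
#' @param type `"aic"` (default) or `"aicc"`.
#' @export
gwr_aic <- function(fit, type = c("aic", "aicc")) {
  type <- match.arg(type)
  if (type == "aic") fit$aic else fit$aicc
}

#' Select the adaptive bandwidth by minimizing AIC
#'
#' Golden-section search over the integer neighbour count N, assuming an
#' approximately unimodal AIC profile; if the evaluated trace turns out
#' non-unimodal, the search falls back to a coarse grid of 20 log-spaced
#' candidates with local refinement around the grid minimum. Ties are
#' broken toward the larger (smoother) bandwidth.
#'
#' @param X,y,points as in [fit_gwr()].
#' @param candidates integer range `c(lo, hi)`; defaults to
#'   `[p + 2, n - 1]`.
#' @param criterion `"aic"` (default) or `"aicc"`.
#' @param half passed to [kernel_spec()].
#' @param verbose print the trace as it is evaluated.
#' @return list with `kernel` (the selected [kernel_spec()]), `N`,
#'   `criterion`, and `trace` (data.frame of evaluated N and AIC).
#' @export
select_bandwidth <- function(X, y, points, candidates = NULL,
                             criterion = c("aic", "aicc"), half = FALSE,
                             verbose = FALSE) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(candidates)) candidates <- c(p + 2L, n - 1L)
  lo <- max(as.integer(candidates[1]), p + 2L)
  hi <- min(as.integer(candidates[2]), n)
  if (lo >= hi) stop("empty bandwidth candidate range")

  cache <- new.env(parent = emptyenv())
  eval_N <- function(N) {
    key <- as.character(N)
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- tryCatch(
      gwr_aic(fit_gwr(X, y, points, kernel_spec(N, half = half)),
              type = criterion),
      error = function(e) Inf)
    cache[[key]] <- val
    if (verbose) message(sprintf("  N = %d  %s = %.2f", N,
                                 toupper(criterion), val))
    val
  }

  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- round(b - phi * (b - a)); x2 <- round(a + phi * (b - a))
  while (b - a > 2L) {
    f1 <- eval_N(x1); f2 <- eval_N(x2)
    if (f1 < f2) {  # strict: ties move the bracket up, toward larger N
      b <- x2; x2 <- x1; x1 <- round(b - phi * (b - a))
    } else {
      a <- x1; x1 <- x2; x2 <- round(a + phi * (b - a))
    }
    if (x1 >= x2) { x1 <- max(a, x2 - 1L); }
  }
  for (N in a:b) eval_N(N)

  trace <- data.frame(N = as.integer(ls(cache)),
                      aic = vapply(ls(cache), function(k) cache[[k]],
                                   numeric(1)))
  trace <- trace[order(trace$N), ]
  rownames(trace) <- NULL

  if (!is_unimodal(trace$aic)) {
    grid <- unique(round(exp(seq(log(lo), log(hi), length.out = 20))))
    for (N in grid) eval_N(N)
    trace <- data.frame(N = as.integer(ls(cache)),
                        aic = vapply(ls(cache), function(k) cache[[k]],
                                     numeric(1)))
    trace <- trace[order(trace$N), ]
    best <- trace$N[which.min(trace$aic)]
    nb <- sort(unique(pmin(pmax(best + c(-8:-1, 1:8), lo), hi)))
    for (N in nb) eval_N(N)
    trace <- data.frame(N = as.integer(ls(cache)),
                        aic = vapply(ls(cache), function(k) cache[[k]],
                                     numeric(1)))
    trace <- trace[order(trace$N), ]
    rownames(trace) <- NULL
  }

  finite <- is.finite(trace$aic)
  if (!any(finite)) stop("no bandwidth candidate produced a valid fit")
  best_aic <- min(trace$aic[finite])
  # ties (within numerical noise) resolved toward the larger N
  N_best <- max(trace$N[finite & trace$aic <= best_aic + 1e-9])
  list(kernel = kernel_spec(N_best, half = half), N = N_best,
       criterion = criterion, trace = trace)
}

# tolerant unimodality check on an AIC trace: decreasing then increasing,
# allowing small (< 2 units) local wiggles from integer rounding
is_unimodal <- function(v, slack = 2) {
  k <- which.min(v)
  pre <- v[seq_len(k)]
  post <- v[k:length(v)]
  all(diff(pre) <= slack) && all(diff(post) >= -slack)
}

#' Stationarity index of local GWR coefficients
#'
#' For each model term, the five-number summary of the local coefficient
#' estimates and the stationarity index
#' `SI = IQR / (2 * SE_global)`, the interquartile range of the local
#' estimates divided by twice the standard error of the same term in the
#' global logistic model. SI > 1 flags significant spatial
#' nonstationarity of that term (roughly a 5 percent level: the IQR of
#' the local estimates exceeds a +/- 1 SE band around the global
#' estimate).
#'
#' @param gwr a `gwr_fit`.
#' @param global_fit a `global_logistic_fit` on the same covariates in
#'   the same order.
#' @return data.frame with columns `variable`, `minimum`,
#'   `lower_quartile`, `median`, `upper_quartile`, `maximum`, `si`.
#' @export
stationarity_index <- function(gwr, global_fit) {
  B <- gwr$local_coefficients
  se_g <- global_fit$standard_errors
  if (!identical(colnames(B), names(global_fit$coefficients)))
    stop("covariate ordering differs between the GWR and global fits")
  if (any(se_g <= 0)) stop("degenerate global fit: zero standard error")
  qs <- apply(B, 2, stats::quantile,
              probs = c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE)
  iqr <- qs[4, ] - qs[2, ]
  data.frame(variable = colnames(B),
             minimum = qs[1, ], lower_quartile = qs[2, ], median = qs[3, ],
             upper_quartile = qs[4, ], maximum = qs[5, ],
             si = iqr / (2 * se_g), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Local significance mask
#'
#' Two-sided normal-approximation test of each local t-value; entry
#' (i, k) is TRUE where the local p-value is strictly below `alpha`.
#'
#' @param gwr a `gwr_fit`.
#' @param alpha significance level (default 0.05).
#' @return n x (p+1) logical matrix.
#' @export
local_significance <- function(gwr, alpha = 0.05) {
  p_val <- 2 * stats::pnorm(-abs(gwr$local_t_values))
  p_val < alpha
}
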