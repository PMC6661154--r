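# Fixture builders shared across test files. Everything is generated in
# code at test time; no stored data.

# small logistic dataset with known linear truth on scattered points
make_logistic_fixture <- function(n = 50, p = 2, beta = NULL, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  if (is.null(beta)) beta <- c(0.2, seq_len(p) / p)
  eta <- drop(cbind(1, X) %*% beta)
  y <- rbinom(n, 1, plogis(eta))
  # guard: both classes present (resample deterministically if not)
  while (length(unique(y)) < 2) y <- rbinom(n, 1, plogis(eta))
  pts <- data.frame(x = runif(n, 0, 1e5), y = runif(n, 0, 3e4))
  list(X = X, y = y, beta = beta, points = pts)
}

# brute-force weighted-likelihood maximizer: independent of the IRLS path
optim_logistic <- function(X, y, w = rep(1, length(y))) {
  Z <- cbind(1, as.matrix(X))
  nll <- function(b) {
    eta <- drop(Z %*% b)
    -sum(w * (y * eta - log1p(exp(eta))))
  }
  gr <- function(b) {
    mu <- plogis(drop(Z %*% b))
    -drop(crossprod(Z, w * (y - mu)))
  }
  o <- optim(numeric(ncol(Z)), nll, gr, method = "BFGS",
             control = list(reltol = 1e-15, maxit = 2000))
  o$par
}

# two clearly separated Gaussian blobs in q dimensions; separation on
# every axis so the contrast survives per-column z-scoring
make_blobs <- function(n_per = 40, q = 2, sep = 8, seed = 1) {
  set.seed(seed)
  F <- rbind(matrix(rnorm(n_per * q), n_per, q),
             matrix(rnorm(n_per * q), n_per, q) + sep)
  list(features = F, membership = rep(1:2, each = n_per))
}

# regular grid of points (metres)
make_grid_points <- function(nx = 10, ny = 10, spacing = 1) {
  g <- expand.grid(x = seq_len(nx) - 1, y = seq_len(ny) - 1)
  g * spacing
}
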