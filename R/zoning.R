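#' K-means zoning of local regression results
#'
#' Clusters the per-location GWR results (t-values or coefficient
#' estimates) into k zones of similar species-environment relationships.
#' Columns are z-scored before clustering so no variable dominates by
#' scale; the best of `n_init` Lloyd runs by within-cluster sum of
#' squares is kept, and cluster labels are renumbered by decreasing
#' cluster size so repeated runs compare stably.
#'
#' @param features n x q numeric matrix (rows = locations).
#' @param k number of clusters.
#' @param n_init number of random restarts (default 25).
#' @param seed RNG seed.
#' @return list with `labels`, `centers` (z-score space), `sizes`,
#'   `inertia` (total within-cluster SS).
#' @export
kmeans_zones <- function(features, k, n_init = 25L, seed = 1L) {
  F0 <- as.matrix(features)
  if (any(!is.finite(F0))) stop("non-finite features")
  n_distinct <- nrow(unique(F0))
  if (k > n_distinct) stop("k exceeds the number of distinct rows")
  Fz <- scale(F0)
  Fz[, attr(Fz, "scaled:scale") == 0] <- 0  # constant columns carry no signal
  set.seed(seed)
  if (k == 1L) {
    ctr <- colMeans(Fz)
    return(list(labels = rep(1L, nrow(Fz)), centers = rbind(ctr),
                sizes = nrow(Fz),
                inertia = sum(sweep(Fz, 2, ctr)^2)))
  }
  # empty-cluster warnings from single Lloyd restarts are noise when
  # nstart retries; the best-inertia solution is what counts
  km <- suppressWarnings(stats::kmeans(Fz, centers = k, nstart = n_init,
                                       algorithm = "Lloyd",
                                       iter.max = 200L))
  ord <- order(km$size, decreasing = TRUE)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  list(labels = relabel[km$cluster],
       centers = km$centers[ord, , drop = FALSE],
       sizes = km$size[ord],
       inertia = km$tot.withinss)
}

#' Gap statistic for the number of zones
#'
#' Tibshirani's gap statistic: within-cluster dispersion of the observed
#' features is compared with that of B reference sets drawn uniformly
#' over the per-column range, and the selected k is the smallest k with
#' `gap(k) >= gap(k+1) - SE(k+1)` (the one-standard-error rule).
#' Computed with `cluster::clusGap` over the same z-scored feature space
#' that [kmeans_zones()] uses.
#'
#' @param features n x q numeric matrix.
#' @param k_max largest k considered (>= 2).
#' @param B number of uniform reference draws (default 100).
#' @param n_init k-means restarts per evaluation.
#' @param seed RNG seed.
#' @return list with `gap_curve` (data.frame k, logW, E_logW, gap, se)
#'   and `selected_k`.
#' @export
gap_statistic <- function(features, k_max, B = 100L, n_init = 25L,
                          seed = 1L) {
  stopifnot(k_max >= 2)
  F0 <- as.matrix(features)
  Fz <- scale(F0)
  if (any(attr(Fz, "scaled:scale") == 0))
    stop("degenerate (constant) feature column")
  set.seed(seed)
  cg <- cluster::clusGap(
    Fz,
    FUNcluster = function(x, k) {
      if (k == 1L) list(cluster = rep(1L, nrow(x)))
      # Lloyd restarts on uniform reference draws routinely hit empty
      # clusters; nstart already retries, so the warning is just noise
      else suppressWarnings(stats::kmeans(x, k, nstart = n_init,
                                          algorithm = "Lloyd",
                                          iter.max = 200L))
    },
    K.max = k_max, B = B, d.power = 2, spaceH0 = "original",
    verbose = FALSE)
  tab <- as.data.frame(cg$Tab)
  sel <- cluster::maxSE(tab$gap, tab$SE.sim, method = "Tibs2001SEmax")
  list(gap_curve = data.frame(k = seq_len(k_max), logW = tab$logW,
                              E_logW = tab$E.logW, gap = tab$gap,
                              se = tab$SE.sim),
       selected_k = sel)
}

#' Inverse-distance-weighted interpolation to a regular grid
#'
#' Interpolates per-location values (local coefficients or t-values) to
#' a regular grid for mapping, as an inverse-distance-power weighted mean
#' of the nearest samples. A grid cell coinciding with a sample point
#' takes that sample's value exactly, and cells farther than `cutoff`
#' from every sample are masked (outside the surveyed domain).
#'
#' @param points data.frame with columns `x`, `y` (metres).
#' @param values numeric vector, one value per point.
#' @param spacing grid spacing in metres (default 2000).
#' @param power inverse-distance exponent (default 2).
#' @param max_neighbors number of nearest samples used per cell
#'   (default 12).
#' @param cutoff mask distance in metres (default 5000).
#' @return object of class `coefficient_grid`: list with `x`, `y` (cell
#'   centre coordinates), `values` (r x c matrix, rows = y), `mask`.
#' @export
idw_interpolate <- function(points, values, spacing = 2000, power = 2,
                            max_neighbors = 12L, cutoff = 5000) {
  P <- as.matrix(points[, c("x", "y")])
  n <- nrow(P)
  stopifnot(length(values) == n, n >= 1)
  gx <- seq(min(P[, 1]), max(P[, 1]), by = spacing)
  gy <- seq(min(P[, 2]), max(P[, 2]), by = spacing)
  if (length(gx) == 0L || length(gy) == 0L) stop("empty grid")
  m <- max_neighbors
  V <- matrix(NA_real_, length(gy), length(gx))
  M <- matrix(FALSE, length(gy), length(gx))
  for (r in seq_along(gy)) {
    dy2 <- (P[, 2] - gy[r])^2
    for (cc in seq_along(gx)) {
      d2 <- (P[, 1] - gx[cc])^2 + dy2
      o <- order(d2)[seq_len(min(m, n))]
      d <- sqrt(d2[o])
      if (d[1] > cutoff) next
      M[r, cc] <- TRUE
      if (d[1] < 1e-9) {
        V[r, cc] <- values[o[1]]
      } else {
        w <- 1 / d^power
        V[r, cc] <- sum(w * values[o]) / sum(w)
      }
    }
  }
  structure(list(x = gx, y = gy, values = V, mask = M,
                 spacing = spacing),
            class = "coefficient_grid")
}

#' Cross-tabulate zoning clusters against reference regions
#'
#' Compares the data-driven zones with an a priori regionalization
#' (basins or management units): contingency table of cluster x region
#' and the purity of each region (share of its most common cluster).
#'
#' @param labels integer cluster labels per sample point.
#' @param region_labels region identifier per sample point, same length.
#' @return list with `table` (cluster x region counts) and `purity`
#'   (named per-region vector).
#' @export
zone_report <- function(labels, region_labels) {
  if (length(labels) != length(region_labels))
    stop("labels and region_labels differ in length")
  tab <- table(cluster = labels, region = region_labels)
  purity <- apply(tab, 2, function(cnt) max(cnt) / sum(cnt))
  list(table = tab, purity = purity)
}
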