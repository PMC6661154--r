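#' Coefficient / intercept surface constructors
#'
#' Spatially varying (or constant) surfaces used by the synthetic survey
#' generator: a constant, a linear west-to-east ramp, or a Gaussian bump.
#' Surfaces are evaluated on normalized domain coordinates, so they are
#' independent of the physical domain extents.
#'
#' @param value constant value.
#' @name surfaces
#' @export
surface_constant <- function(value) {
  structure(list(type = "constant", value = value), class = "surface")
}

#' @rdname surfaces
#' @param west,east surface values at the western and eastern domain
#'   edges; linear in between.
#' @export
surface_ramp <- function(west, east) {
  structure(list(type = "ramp", west = west, east = east),
            class = "surface")
}

#' @rdname surfaces
#' @param cx,cy bump centre in normalized coordinates (0-1).
#' @param width bump standard deviation in normalized units.
#' @param height bump amplitude (added to `base`).
#' @param base background level.
#' @export
surface_bump <- function(cx, cy, width, height, base = 0) {
  structure(list(type = "bump", cx = cx, cy = cy, width = width,
                 height = height, base = base),
            class = "surface")
}

eval_surface <- function(s, tx, ty) {
  switch(s$type,
         constant = rep(s$value, length(tx)),
         ramp = s$west + (s$east - s$west) * tx,
         bump = s$base + s$height *
           exp(-((tx - s$cx)^2 + (ty - s$cy)^2) / (2 * s$width^2)),
         stop("unknown surface type"))
}

surface_is_constant <- function(s) {
  s$type == "constant" || (s$type == "ramp" && s$west == s$east) ||
    (s$type == "bump" && s$height == 0)
}

#' Specification of a synthetic presence/absence survey
#'
#' Describes an elongated two-dimensional lake-like domain, four
#' environmental covariate fields with broad west-east gradients plus
#' independent Gaussian noise, and per-covariate coefficient surfaces on
#' the logit scale. Coefficient surfaces act on covariate *anomalies*
#' (departures from the realized sample mean), which keeps the linear
#' predictor bounded while the covariates stay in realistic physical
#' units; the raw-scale intercept implied by this centring is stored in
#' the generated `true_beta` matrix so that
#' `true_probability = plogis(true_beta %*% c(1, x))` holds exactly.
#'
#' Default field gradients mimic the study system qualitatively:
#' temperature decreasing west to east, depth and transparency
#' increasing, dissolved oxygen spatially flat, with noise levels that
#' keep pairwise VIFs well below 2.
#'
#' @param n_points number of sampling locations (>= 50).
#' @param domain extents in metres, `c(width, height)`; the default
#'   400 km x 90 km is elongated like the study lake.
#' @param covariate_fields named list; each element is
#'   `list(west=, east=, noise_sd=, lower=, upper=)` describing a linear
#'   west-east mean field, the noise SD, and physical truncation bounds.
#' @param coefficient_surfaces named list of [surfaces] (one per
#'   covariate, anomaly scale).
#' @param intercept_surface a [surfaces] object for the logit intercept.
#' @param years calendar years to sample from (i.i.d. by default).
#' @param seed integer RNG seed (R's default Mersenne-Twister stream, so
#'   datasets are reproducible across platforms).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(
    n_points = 1000L,
    domain = c(400000, 90000),
    covariate_fields = list(
      temperature = list(west = 24, east = 18, noise_sd = 1.7,
                         lower = 4, upper = 32),
      depth = list(west = 15, east = 45, noise_sd = 8,
                   lower = 2, upper = 70),
      transparency = list(west = 1.5, east = 5.5, noise_sd = 1.1,
                          lower = 0.1, upper = 12),
      dissolved_oxygen = list(west = 8, east = 8, noise_sd = 1,
                              lower = 0.5, upper = 14)),
    coefficient_surfaces = list(
      temperature = surface_ramp(-0.4, 0.3),
      depth = surface_ramp(0.12, -0.16),
      transparency = surface_constant(-0.25),
      dissolved_oxygen = surface_constant(0)),
    intercept_surface = surface_constant(1.4),
    years = 1989:2015,
    seed = 1L) {
  stopifnot(n_points >= 50, all(domain > 0),
            identical(names(covariate_fields), names(coefficient_surfaces)))
  for (f in covariate_fields) stopifnot(f$noise_sd >= 0)
  structure(list(n_points = as.integer(n_points), domain = domain,
                 covariate_fields = covariate_fields,
                 coefficient_surfaces = coefficient_surfaces,
                 intercept_surface = intercept_surface,
                 years = years, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic survey dataset with known coefficient surfaces
#'
#' Draws sampling locations uniformly over the domain, builds the
#' covariate fields (west-east linear mean plus truncated Gaussian
#' noise), evaluates the true coefficient surfaces at every location and
#' draws presence/absence from the implied Bernoulli probabilities.
#' Bit-identical for a given spec (including its seed).
#'
#' @param spec a [synthetic_spec()].
#' @return object of class `synthetic_dataset`: list with `points`
#'   (data.frame x, y), `X` (covariate matrix), `true_beta`
#'   (n x (p+1), raw-covariate scale, intercept first), `true_probability`,
#'   `y`, `year`, `spec`.
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_points
  x <- stats::runif(n, 0, spec$domain[1])
  y_coord <- stats::runif(n, 0, spec$domain[2])
  tx <- x / spec$domain[1]
  ty <- y_coord / spec$domain[2]

  covs <- names(spec$covariate_fields)
  X <- sapply(covs, function(v) {
    f <- spec$covariate_fields[[v]]
    val <- f$west + (f$east - f$west) * tx +
      stats::rnorm(n, 0, f$noise_sd)
    pmin(pmax(val, f$lower), f$upper)  # truncate to physical bounds
  })
  colnames(X) <- covs

  beta_cov <- sapply(covs, function(v)
    eval_surface(spec$coefficient_surfaces[[v]], tx, ty))
  beta0_anom <- eval_surface(spec$intercept_surface, tx, ty)
  xbar <- colMeans(X)
  # fold the anomaly centring into the raw-scale intercept column
  beta0_raw <- beta0_anom - drop(beta_cov %*% xbar)
  true_beta <- cbind(`(Intercept)` = beta0_raw, beta_cov)

  eta <- beta0_raw + rowSums(beta_cov * X)
  if (any(abs(eta) > 30))
    stop("degenerate spec: |logit| exceeds 30 somewhere in the domain")
  p_true <- stats::plogis(eta)
  presence <- stats::rbinom(n, 1, p_true)
  year <- sample(spec$years, n, replace = TRUE)

  structure(list(points = data.frame(x = x, y = y_coord),
                 X = X, true_beta = true_beta,
                 true_probability = p_true, y = presence, year = year,
                 spec = spec),
            class = "synthetic_dataset")
}

#' Which coefficient surfaces actually vary in space?
#'
#' @param spec a [synthetic_spec()].
#' @return named logical vector over the covariates.
#' @export
varying_covariates <- function(spec) {
  !vapply(spec$coefficient_surfaces, surface_is_constant, logical(1))
}

#' Stationary-null synthetic dataset
#'
#' Convenience wrapper around [generate()] with all coefficient surfaces
#' constant (spatially stationary truth); used to calibrate the
#' stationarity index and bandwidth selection. The default constant
#' effects are of the magnitude a global logistic fit to such survey
#' data would report.
#'
#' @param ... overrides passed to [synthetic_spec()].
#' @export
stationary_null <- function(...) {
  args <- list(...)
  if (is.null(args$coefficient_surfaces))
    args$coefficient_surfaces <- list(
      temperature = surface_constant(0.15),
      depth = surface_constant(0.05),
      transparency = surface_constant(-0.3),
      dissolved_oxygen = surface_constant(0.1))
  if (is.null(args$intercept_surface))
    args$intercept_surface <- surface_constant(0.4)
  generate(do.call(synthetic_spec, args))
}

#' Named synthetic presets
#'
#' `"nonstationary"`: the default spec (temperature and depth effects
#' ramp west to east, temperature flipping sign along the way);
#' `"stationary"`: all effects constant; `"ramp-flip"`: only the
#' temperature effect varies (sign-flipping ramp), everything else
#' constant.
#'
#' @param preset one of `"nonstationary"`, `"stationary"`, `"ramp-flip"`.
#' @param ... overrides passed to [synthetic_spec()].
#' @export
synthetic_preset <- function(preset = c("nonstationary", "stationary",
                                        "ramp-flip"), ...) {
  preset <- match.arg(preset)
  switch(preset,
         nonstationary = generate(synthetic_spec(...)),
         stationary = stationary_null(...),
         `ramp-flip` = {
           args <- list(...)
           args$coefficient_surfaces <- list(
             temperature = surface_ramp(-0.4, 0.3),
             depth = surface_constant(0.05),
             transparency = surface_constant(-0.3),
             dissolved_oxygen = surface_constant(0.1))
           generate(do.call(synthetic_spec, args))
         })
}

#' Write a synthetic dataset in the survey CSV dialect
#'
#' Emits a CSV that [read_survey()] reads back losslessly (projected
#' `x`, `y` coordinates, the four covariates, year and the presence
#' flag), plus a sidecar CSV holding the true coefficient surfaces for
#' scoring parameter recovery.
#'
#' @param ds a `synthetic_dataset`.
#' @param path output CSV path.
#' @param truth_path sidecar path for the true coefficients (default:
#'   `path` with `_truth` appended before the extension).
#' @return invisibly, the two paths.
#' @export
write_survey_csv <- function(ds, path,
                             truth_path = sub("(\\.[^.]+)?$", "_truth\\1",
                                              path)) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  out <- data.frame(x = ds$points$x, y = ds$points$y, year = ds$year,
                    ds$X, presence = ds$y, check.names = FALSE)
  truth <- data.frame(x = ds$points$x, y = ds$points$y, ds$true_beta,
                      true_probability = ds$true_probability,
                      check.names = FALSE)
  # 17 significant digits makes the double round trip bit-exact
  fmt <- function(d) {
    d[] <- lapply(d, function(v) if (is.double(v)) sprintf("%.17g", v) else v)
    d
  }
  utils::write.csv(fmt(out), path, row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(truth), truth_path, row.names = FALSE, quote = FALSE)
  invisible(c(path, truth_path))
}
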