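---
title: "Local models for nonstationary species-environment relationships"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local models for nonstationary species-environment relationships}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(perchgwr)
```

## The problem

A fish's response to its environment is usually summarized by one
regression fitted to an entire survey region: one temperature
coefficient, one depth coefficient, for the whole lake. In a large,
heterogeneous system that average can be a fiction — a species may seek
warmer water where the lake is cold and avoid it where the lake is
already warm, and the pooled coefficient then lands somewhere near zero.
This package explores that *spatial nonstationarity* for presence/absence
survey data, with Great Lakes gillnet surveys of Yellow Perch as the
motivating system: records of presence or absence by life stage
(juveniles younger than age 2, the recruitment age; adults at age 2 and
older) together with bottom water temperature (°C), water depth (m),
Secchi transparency (m) and dissolved oxygen (mg/L).

## The model

The workhorse is a geographically weighted logistic regression (GWR).
At every sample location $i$ with projected coordinates $(u_i, v_i)$ a
separate logistic model

$$\log\frac{p_i}{1-p_i} = \beta_0(u_i, v_i) +
  \sum_{k} \beta_k(u_i, v_i)\, x_{k}$$

is fitted by maximizing the *kernel-weighted* binomial likelihood, with
weights that decay with distance from the regression point:

$$w_{ij} = \exp\!\left(-\,d_{ij}^2 / h_i\right),$$

$d_{ij}$ the Euclidean distance between sites on the UTM plane. The
bandwidth is *adaptive*: $h_i$ is the squared distance from site $i$ to
its $N$-th nearest neighbour, so the kernel narrows where sampling is
dense. One integer $N$ governs the whole fit and is chosen by minimizing
$\mathrm{AIC} = D + 2\,\mathrm{tr}(S)$, where $D$ is the model deviance
(each observation evaluated under its own local fit) and
$\mathrm{tr}(S)$, the trace of the hat matrix of the local-fit ensemble,
is the effective number of parameters. The small-sample corrected AICc
is computed alongside and can be selected via
`select_bandwidth(criterion = "aicc")`.

Two conventions coexist for the Gaussian kernel: the form above, in
which $h$ is a squared-distance scale, and a half-exponent variant
$\exp(-d^2/2h)$ used by some GWR software. The package defaults to the
former and exposes the latter as `half = TRUE` in `kernel_spec()`; at an
AIC-selected bandwidth the two differ only by a rescaling of the
selected $N$.

Each local fit is an iteratively reweighted least squares (IRLS)
maximization of the weighted likelihood, with standard errors from the
inverse weighted Fisher information. Small effective samples make local
separation common, so the solver falls back to a tiny L2 ridge
($10^{-6}$, slopes only) when the unpenalized likelihood has no finite
maximizer, and flags the location; a location whose total weight is too
small to support $p+1$ parameters, or whose weighted response is
single-class, is marked unestimable. A fit with more than 5% unestimable
locations errors with a suggestion to widen the bandwidth.

### Stationarity index

Whether an effect genuinely varies in space is judged by the
stationarity index: the interquartile range of a coefficient's local
estimates divided by twice the standard error of the same coefficient in
the global logistic model,

$$\mathrm{SI}_k = \frac{\mathrm{IQR}(\hat\beta_k(u, v))}
  {2\,\mathrm{se}(\hat\beta_k^{global})},$$

with SI > 1 read as significant nonstationarity at roughly the 5% level.
A caveat this package's simulations make explicit: SI is well calibrated
when the *whole* fit is stationary (all SI below 1 on stationary truths),
but once the bandwidth adapts to genuine nonstationarity in some terms,
the local sampling noise of a *truly constant* term also inflates, and
its SI frequently exceeds 1. SI separates varying from constant effects
by magnitude (values of 5–15 versus values near 1 in our conditions)
rather than by a sharp threshold.

### Baselines

Two global models calibrate the comparison. An ordinary logistic
regression supplies the SI denominator and the infinite-bandwidth limit
of the GWR. A binomial additive model with one penalized cubic
regression spline per covariate (basis dimension 10, smoothness selected
automatically with the effective degrees of freedom inflated by
gamma = 1.4 to resist overfitting, via mgcv) represents the strongest
*stationary* competitor: it can bend the response curve but applies the
same curve everywhere.

### Diagnostics

Goodness of fit is reported as AIC and deviance explained
$(D_0 - D)/D_0$; discrimination as the area under the ROC curve in its
Mann–Whitney form (ties counted one half). Predictive accuracy uses 100
repeats of a random 3:1 train/test split; the GWR refits at training
locations and scores a test point with its nearest training location's
coefficient vector — a deliberate choice over refitting at test
locations, which costs an order of magnitude more and changes CV AUC
negligibly at these sample sizes (no test labels are involved either
way). Residual spatial structure is tested with Moran's I on a binary
row-standardized 8-nearest-neighbour graph and a two-sided permutation
p-value $(1 + \#\{|I_\pi| \ge |I_{obs}|\})/(1 + B)$; the neighbour
count and the use of deviance residuals are defaults, both configurable,
since no single convention is canonical. Pooling a multi-decade survey
into one spatial fit leaves year effects unmodelled, so residuals are
also summarized per year with a one-way ANOVA across years.

### Zoning

To turn the local estimates into management-relevant geography, the
per-location t-values of the environmental effects (the intercept is
excluded by default; `feature_source` can switch to raw coefficients)
are z-scored per column and clustered by k-means (best of 25 Lloyd
restarts; labels renumbered by cluster size for determinism). The number
of zones is selected by the gap statistic — uniform reference sets over
the per-column range, $B = 100$ draws, smallest $k$ with
$\mathrm{gap}(k) \ge \mathrm{gap}(k+1) - \mathrm{SE}(k+1)$. Coefficient
surfaces are interpolated to a 2-km grid by inverse-distance weighting
(power 2, 12 neighbours, cells more than 5 km from any sample masked);
kriging was deliberately left out, as the maps are descriptive and IDW
honours the exact-hit and convexity properties the tests rely on.

## The synthetic study conditions

Real survey deposits cannot be redistributed here, so every claim is
exercised on a synthetic survey whose generator is itself first-class,
tested code. It emulates the structure of the real system: an elongated
400 km × 90 km domain; uniformly placed sampling points; four covariate
fields with broad west-east linear gradients plus independent Gaussian
noise, truncated to physical bounds — temperature 24→18 °C (sd 1.7),
depth 15→45 m (sd 8), transparency 1.5→5.5 m (sd 1.1), dissolved oxygen
flat at 8 mg/L (sd 1). The noise levels were sized so that all variance
inflation factors stay below 2, the regime reported for the real
covariates. Coefficient surfaces act on covariate anomalies (departures
from the sample mean), which keeps the logit bounded while fields stay
in physical units; the raw-scale intercept implied by that centring is
folded into the stored `true_beta`, so
`true_probability = plogis(true_beta %*% c(1, x))` holds exactly.

The `nonstationary` preset ramps the temperature effect from −0.4 in the
west to +0.3 in the east (a sign flip mid-lake, with amplitudes in the
range reported for juvenile Yellow Perch) and the depth effect from
+0.12 to −0.16, holds transparency at −0.25 and dissolved oxygen at 0,
and sets the anomaly-scale intercept to 1.4 so simulated prevalence sits
near the 58% observed for juveniles. The `stationary` preset holds all
effects constant; `ramp-flip` varies only temperature. What the
generator does *not* emulate: depth-stratified site placement, gillnet
selectivity, and year effects (a year column is emitted but is i.i.d.),
so passing tests speak to the estimator's behaviour under known smooth
nonstationarity, not to survey-design artefacts.

## Numerical choices

* IRLS converges on an absolute deviance change below $10^{-8}$, capped
  at 100 iterations; fitted probabilities are clamped to
  $[10^{-12}, 1-10^{-12}]$ before the variance weights are formed.
* An exit with any $|\eta| > 30$ on an unpenalized fit is treated as
  separation (the MLE is off at infinity) and triggers the ridge.
* Local fits warm-start from the global coefficients, and observations
  with kernel weight below $10^{-9}$ are dropped from a local fit (the
  regression point itself is always kept); at the global-limit bandwidth
  nothing is dropped, preserving the exact-limit equivalence.
* Bandwidth search is golden-section on the integer neighbour count over
  $[p+2, n-1]$, with AIC ties broken toward the larger (smoother) $N$;
  if the evaluated trace is not unimodal (within a 2-unit slack) the
  search falls back to a 20-point log-spaced grid with local refinement.
* Tied distances in the adaptive scale resolve by value, so equidistant
  neighbours are interchangeable; duplicate coordinates are legitimate
  (several gillnet sets at one site) and count as neighbours at distance
  zero.
* Cleaning marks as erroneous: any missing mandatory field, temperature
  outside [0, 35] °C, depth ≤ 0, transparency < 0, dissolved oxygen < 0.
  The bounds are physically forced and configurable; no published rule
  exists for which raw records were discarded, so row-count replication
  of a given survey can only be approximate.
* The UTM projection (zone 17N, GRS80) is implemented from the standard
  transverse Mercator series, accurate to well under a metre at lake
  scale; no projection library is required.

## Problem sizes

The shipped tests and the acceptance script run the pipeline at sizes
chosen to keep a full run on one CPU comfortable while leaving the
conclusions stable: the headline fit and recovery checks at $n = 1000$;
calibration sweeps (stationarity index over 10 seeds per regime,
bandwidth-selection behaviour) at $n = 500$–600; Moran calibration with
199 permutations over 500 replicates; gap-statistic checks with
$B = 100$. The analysis scripts under `analysis/` use $n = 1000$
throughout.

## Known limitations

* Regression points are the sample points only; prediction at unsampled
  grid nodes is by surface interpolation, never by refitting, and the
  model cannot extrapolate outside the surveyed domain.
* Local coefficients at neighbouring sites share most of their data, so
  mapped surfaces are smooth by construction and their pointwise
  significance masks are not simultaneous inference.
* The SI caveat above: on a nonstationary fit, SI > 1 for a given term
  is evidence that *some* of the fit varies, not proof that that term
  does.
* The gap statistic presumes discrete cluster structure. Local
  coefficients that vary *smoothly* (as in the synthetic ramps) have no
  true k, and the gap curve then keeps rising with k; on such data the
  selected k describes resolution, not distinct regimes. Discrete zone
  counts are meaningful when the underlying relationships really do fall
  into regimes, which is exactly what separated-blob truths (and the
  tests) exercise.
* Fixed (metric) bandwidths are supported but untuned; bisquare or
  exponential kernels, mixed (partially stationary) GWR, and
  geographically weighted models for counts are out of scope, as are
  spatio-temporal (GTWR) extensions.
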