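# perchgwr

Species distribution models are usually *global*: one logistic (or
additive) regression is fitted to a whole survey region, so each
environmental variable gets a single coefficient everywhere. In a large,
heterogeneous system — the motivating case is Yellow Perch
(*Perca flavescens*) presence/absence in Lake Erie gillnet surveys —
that average can hide opposite responses in different basins: fish that
seek warmer water where the lake is cold may avoid it where the lake is
already warm. `perchgwr` implements the local alternative, a
**geographically weighted logistic regression (GWR)**, together with
everything needed to run and judge such an analysis end to end.

At each sample location *i* a separate logistic model

    logit(p_i) = beta_0(u_i, v_i) + sum_k beta_k(u_i, v_i) * x_k

is fitted by kernel-weighted maximum likelihood, with Gaussian weights
`w_ij = exp(-d_ij^2 / h_i)` and an adaptive bandwidth: `h_i` is the
squared distance to the *N*-th nearest neighbour, and the single integer
*N* is chosen by minimizing `AIC = deviance + 2 tr(S)` (trace of the hat
matrix = effective number of parameters). Spatial nonstationarity of
each effect is quantified by the stationarity index
`SI = IQR(local estimates) / (2 * SE_global)`, with SI > 1 read as
significantly nonstationary. The package also provides:

* survey ingestion, cleaning and presence coding by life stage, UTM
  zone 17N projection (built-in transverse Mercator), and VIF screening
  (`read_survey`, `clean_survey`, `project_coordinates`, `compute_vif`);
* global logistic and penalized-cubic-spline additive baselines
  (`fit_global_logistic`, `fit_gam` via mgcv with gamma = 1.4);
* the GWR core (`fit_gwr`, `select_bandwidth`, `stationarity_index`,
  `local_significance`);
* diagnostics: Mann–Whitney AUC, 100-repeat 3:1 cross-validation,
  Moran's I permutation tests on residuals, residual-by-year ANOVA
  (`auc`, `cross_validate`, `morans_i`, `residuals_by_year`);
* zoning of the local estimates: k-means with gap-statistic selection of
  k and inverse-distance interpolation of coefficient surfaces
  (`kmeans_zones`, `gap_statistic`, `idw_interpolate`, `zone_report`);
* a synthetic survey generator with known spatially varying coefficient
  surfaces, so every stage is testable without any data download
  (`synthetic_preset`, `generate`, `write_survey_csv`).

## Worked example

Simulate a lake-like survey whose temperature effect flips sign from
west to east, pick the bandwidth, fit, and test for nonstationarity:

```r
library(perchgwr)

ds  <- synthetic_preset("nonstationary", n_points = 500, seed = 42)
sel <- select_bandwidth(ds$X, ds$y, ds$points)
fit <- fit_gwr(ds$X, ds$y, ds$points, sel$kernel)
print(fit)
#> Geographically weighted logistic regression
#>   n = 500, covariates: temperature, depth, transparency, dissolved_oxygen
#>   adaptive bandwidth: 113 neighbours
#>   effective parameters: 24.5
#>   deviance: 544.0  AIC: 593.1  AICc: 595.7
#>   deviance explained: 20.2%

glob <- fit_global_logistic(ds$X, ds$y)
stationarity_index(fit, glob)
#>           variable minimum lower_quartile median upper_quartile maximum  si
#> 1      (Intercept)   -0.60          2.193  4.275          5.578   8.564 1.2
#> 2      temperature   -0.40         -0.177 -0.119          0.176   0.315 3.7
#> 3            depth   -0.11         -0.078 -0.015          0.051   0.092 6.5
#> 4     transparency   -0.59         -0.432 -0.170         -0.066   0.068 2.6
#> 5 dissolved_oxygen   -0.43         -0.160 -0.042          0.050   0.307 1.1

auc(fit$fitted_probabilities, ds$y)   # 0.79; the global fit manages 0.61
```

The local temperature coefficients span −0.40 to +0.32 — the designed
sign flip — and the stationarity indices of the two truly varying
effects (temperature, depth) are far above 1, while the global model,
forced to average the flip away, barely discriminates (AUC 0.61 vs
0.79). Bandwidth selection is the slow step (a minute or two at
n = 1000); everything else is seconds.

## The analysis workflow

The `analysis/` directory reruns the study as numbered drivers over the
package, writing tables under `results/`:

1. `01_simulate.R` — nonstationary and stationary synthetic surveys.
2. `02_prepare.R` — ingestion, cleaning, VIF screening.
3. `03_baselines.R` — global logistic and additive-model fits.
4. `04_gwr.R` — bandwidth selection, the GWR fit, stationarity indices,
   recovery of the true coefficient surfaces.
5. `05_diagnostics.R` — cross-validated AUC for all three models,
   Moran's I on residuals, residual-by-year ANOVA.
6. `06_zoning.R` — k-means zones, gap statistic, interpolated
   coefficient-surface grids.

Run them in order with `Rscript analysis/01_simulate.R`, etc.

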