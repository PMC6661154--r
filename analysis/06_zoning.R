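#!/usr/bin/env Rscript
# Step 6: characterize zones of distinct species-environment
# relationships. The per-location t-values of the environmental effects
# are clustered with k-means for k = 2, 3, 4 (for comparison with basins
# and management units), the best k is chosen by the gap statistic, and
# each local coefficient surface is interpolated to a 2-km grid for
# mapping.

library(perchgwr)

d <- read.csv("results/cleaned_nonstationary.csv")
covs <- c("temperature", "depth", "transparency", "dissolved_oxygen")
est <- read.csv("results/gwr_local_estimates.csv", check.names = FALSE)
pts <- d[, c("x", "y")]

X <- as.matrix(d[, covs])
bw <- read.csv("results/gwr_summary.csv")$bandwidth
fit <- fit_gwr(X, d$presence, pts, kernel_spec(bw))
feats <- fit$local_t_values[, -1]  # environmental effects only

zones <- data.frame(pts)
for (k in 2:4) {
  zones[[paste0("label_k", k)]] <-
    kmeans_zones(feats, k, seed = 4)$labels
}
gap <- gap_statistic(feats, k_max = 6, B = 100, seed = 4)
cat("gap statistic curve:\n"); print(gap$gap_curve, digits = 3)
cat(sprintf("selected number of zones: k = %d\n", gap$selected_k))
write.csv(gap$gap_curve, "results/gap_curve.csv", row.names = FALSE)
write.csv(zones, "results/zones.csv", row.names = FALSE)

# a three-way longitudinal split of the domain stands in for the basins
basin <- cut(pts$x, breaks = quantile(pts$x, c(0, 1/3, 2/3, 1)),
             labels = c("west", "central", "east"), include.lowest = TRUE)
zr <- zone_report(zones$label_k3, basin)
cat("\nk = 3 zones against the three longitudinal thirds:\n")
print(zr$table)
cat("per-region purity:\n"); print(round(zr$purity, 3))

# interpolate each coefficient surface to a 2-km grid
for (v in covs) {
  g <- idw_interpolate(pts, fit$local_coefficients[, v])
  gd <- expand.grid(x = g$x, y = g$y)
  gd$value <- as.vector(t(g$values))
  write.csv(gd[!is.na(gd$value), ],
            sprintf("results/surface_beta_%s.csv", v), row.names = FALSE)
}
cat("\nwrote zone labels, gap curve and interpolated coefficient surfaces\n")
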