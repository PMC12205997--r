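#!/usr/bin/env Rscript

# Step 3 — normative lifespan trajectories per metric and scale.
#
# Fits the location-scale-shape model (BCPE family on log10 metrics,
# P-spline age smooths on all four distribution parameters, ridge-shrunk
# site and sex offsets) to every <metric>@<lambda> column of the cohort,
# then writes serialized models, interquartile band CSVs and a fit
# report under results/trajectories/.

library(cortexscales)

co <- read_cohort_csv("results/data/lifespan-cohort/cohort.csv")
fits <- cmd_fit(co, "trajectory", "results/trajectories")

# summarize the scale divergence of the fitted medians
ages <- c(10, 45, 85)
cat("fitted median thickness (mm) by scale:\n")
for (mc in grep("^T@", names(co), value = TRUE)) {
  med <- 10^predict_quantiles(fits[[mc]], ages, 0.5)
  cat(sprintf("  %-9s age 10: %.2f  age 45: %.2f  age 85: %.2f\n",
              mc, med[1], med[2], med[3]))
}
cat("fitted median pial area (mm^2) by scale:\n")
for (mc in grep("^At@", names(co), value = TRUE)) {
  med <- 10^predict_quantiles(fits[[mc]], ages, 0.5)
  cat(sprintf("  %-10s age 10: %8.0f  age 85: %8.0f  (%+.0f%%)\n",
              mc, med[1], med[3], 100 * (med[3] / med[1] - 1)))
}
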