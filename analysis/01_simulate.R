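#!/usr/bin/env Rscript

# Step 1 — generate the synthetic study inputs.
#
# Writes three datasets under results/data/: a smooth concentric-sphere
# pair (geometric oracle), a folded-sphere pair (R = 30 mm, fold
# amplitude 3 mm, angular degree 12: dominant fold wavelength ~15.7 mm),
# and the n = 800 lifespan cohort with two sites and ten metric columns.
# Each directory carries a manifest with the seed and file checksums.

library(cortexscales)

seed <- as.integer(Sys.getenv("CS_SEED", "1"))
root <- "results/data"

for (preset in c("smooth-sphere", "folded-sphere", "lifespan-cohort")) {
  dir <- file.path(root, preset)
  man <- cmd_simulate(dir, preset = preset, seed = seed)
  cat(sprintf("%-16s -> %s (%d files)\n", preset, dir, length(man$files)))
}

co <- read_cohort_csv(file.path(root, "lifespan-cohort", "cohort.csv"))
cat(sprintf("cohort: n = %d, ages %.1f-%.1f, sites: %s\n",
            nrow(co), min(co$age), max(co$age),
            paste(unique(co$site), collapse = ", ")))
cat(sprintf("cor(At@native, age) = %+.3f, cor(At@1.86, age) = %+.3f\n",
            cor(co[["At@native"]], co$age), cor(co[["At@1.86"]], co$age)))
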