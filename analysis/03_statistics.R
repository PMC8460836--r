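#!/usr/bin/env Rscript
# Statistical comparison of simulated conditions with the study's tests:
# two-sample 2D Kolmogorov-Smirnov on (normalized lumen radius, solidity)
# clouds, and exact-matching weights on cells-per-cross-section followed by
# a weighted Welch's t-test.
#
# Uses the condition sweep written by analysis/02_vertex_model.R when
# present (recomputed at 8 seeds otherwise). Observations are pooled over
# all cell numbers, which leaves the conditions imbalanced in N — exactly
# the situation the exact-matching weights correct before testing.
#
# Finding: WT and Cldn-qKO trajectories separate clearly in the 2D KS test,
# and the CEM-weighted Welch tests detect both a lumen-size and a
# lumen-shape difference; pooled over all cell numbers the solidity
# difference is the stronger one, because the low-pressure condition rounds
# up later in growth than the wild type.
#
# Output: results/statistics.json

suppressPackageStartupMessages(library(lumenmorph))
dir.create("results", showWarnings = FALSE)

cond_file <- "results/condition_comparison.csv"
if (file.exists(cond_file)) {
  cond <- read.csv(cond_file)
} else {
  cond <- do.call(rbind, lapply(c("WT", "CldnqKO"), function(nm) {
    pp <- vm_preset(nm)
    out <- vm_sweep(data.frame(p = pp$p, la = pp$la, k = pp$k, lb = pp$lb),
                    seeds = 1:8, n_target = 10)
    out$condition <- nm
    out
  }))
}
cond <- cond[cond$valid, ]
wt <- cond[cond$condition == "WT", ]
qk <- cond[cond$condition == "CldnqKO", ]

# 2D KS on (normalized lumen radius, solidity), as for the experimental
# solidity-vs-size clouds
ks <- ks2d(cbind(wt$normalized_lumen_radius, wt$lumen_solidity),
           cbind(qk$normalized_lumen_radius, qk$lumen_solidity))

# exact matching on cells per cross-section, then weighted Welch
dat <- rbind(
  data.frame(group = "WT", stratum = wt$n_cells,
             area = wt$lumen_area_norm, solidity = wt$lumen_solidity),
  data.frame(group = "CldnqKO", stratum = qk$n_cells,
             area = qk$lumen_area_norm, solidity = qk$lumen_solidity))
# drop the smallest spheroids from one group to mimic class imbalance
dat <- dat[!(dat$group == "CldnqKO" & dat$stratum < 5), ]
w <- cem_weights(dat, reference = "WT")
wwt <- function(col) {
  a <- w[w$group == "WT", ]
  b <- w[w$group == "CldnqKO", ]
  weighted_welch_ttest(a[[col]], a$weight, b[[col]], b$weight)
}
t_area <- wwt("area")
t_sol <- wwt("solidity")

res <- list(
  ks2d_D = unname(ks$statistic), ks2d_p = ks$p.value,
  welch_area_t = unname(t_area$statistic), welch_area_p = t_area$p.value,
  welch_solidity_t = unname(t_sol$statistic), welch_solidity_p = t_sol$p.value,
  n_wt = nrow(wt), n_qko = nrow(qk))
jsonlite::write_json(res, "results/statistics.json", auto_unbox = TRUE,
                     digits = NA)

cat(sprintf("2D KS (r_norm, solidity) WT vs Cldn-qKO: D = %.3f, p = %.2g\n",
            res$ks2d_D, res$ks2d_p))
cat(sprintf("CEM-weighted Welch, lumen area:  t = %6.2f, p = %.2g\n",
            res$welch_area_t, res$welch_area_p))
cat(sprintf("CEM-weighted Welch, solidity:    t = %6.2f, p = %.2g\n",
            res$welch_solidity_t, res$welch_solidity_p))
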