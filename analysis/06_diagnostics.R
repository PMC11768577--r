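#!/usr/bin/env Rscript
# Stage 6 — model qualification.
# IWRES, NPDE, VPC with 90% prediction bands, GOF tables and the
# outlier proportion for the base fit of the PBPK-derived dataset.

library(salbupk)
dir.create("results", showWarnings = FALSE)

dataset <- read_pk_dataset("results/dataset.csv")
init <- init_from_nca(dataset)
fit <- saem_fit(dataset, init = init,
                settings = saem_settings(k1 = 150, k2 = 80), seed = 421)

np <- npde(fit, n_sim = 300, seed = 77)
write.csv(np, "results/npde.csv", row.names = FALSE)
ks <- ks.test(np$npde, "pnorm")
cat(sprintf("NPDE: mean %.3f, SD %.3f, KS p = %.3f\n",
            mean(np$npde), sd(np$npde), ks$p.value))

vp <- vpc(fit, n_sim = 300, bins = 8, seed = 78)
write.csv(vp, "results/vpc.csv", row.names = FALSE)
cat(sprintf("VPC: %d of %d percentile points outside their 90%% bands\n",
            sum(vp$outlier), nrow(vp)))

gof <- gof_tables(fit, np)
write.csv(gof$obs_vs_pred, "results/gof_obs_vs_pred.csv", row.names = FALSE)
write.csv(gof$residuals, "results/gof_residuals.csv", row.names = FALSE)
write.csv(gof$density, "results/gof_density.csv", row.names = FALSE)
cat(sprintf("outlier proportion (outside the 90%% individual interval): %.2f%%\n",
            100 * gof$outlier_proportion))
cat("written: results/npde.csv, vpc.csv, gof_*.csv\n")
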