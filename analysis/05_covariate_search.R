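#!/usr/bin/env Rscript
# Stage 5 — covariate model building.
# Screens the eight candidate covariates (age, weight, BSA, CYP2D6,
# CYP2C19 expression; gender, race, health status) against the EBE
# random effects, filters collinearity by VIF, and runs the stepwise
# forward (-2LL drop > 3.84) / backward (-2LL rise < 10.83) search.

library(salbupk)
dir.create("results", showWarnings = FALSE)

dataset <- read_pk_dataset("results/dataset.csv")
init <- init_from_nca(dataset)
fit <- saem_fit(dataset, init = init,
                settings = saem_settings(k1 = 150, k2 = 80), seed = 421)

ebes <- compute_ebes(fit, quiet = TRUE)
covtab <- do.call(rbind, lapply(fit$data, function(s) s$cov))
scr <- screen_covariates(ebes$eta, covtab)
write.csv(scr, "results/screening.csv", row.names = FALSE)
cat("flagged relationships (p < 0.05):\n")
print(unique(scr[scr$flagged, c("parameter", "covariate")]))

vif <- vif_filter(covtab[, c("AGE", "WT", "BSA", "CYP2D6", "CYP2C19")],
                  threshold = 15,
                  p_values = sapply(c("AGE", "WT", "BSA", "CYP2D6",
                                      "CYP2C19"), function(cv) {
                    sel <- scr$covariate == cv
                    if (any(sel)) min(scr$p_value[sel], na.rm = TRUE) else 1
                  }))
cat("VIF exclusions (multicollinearity):",
    if (length(vif$excluded)) paste(vif$excluded, collapse = ", ") else
      "none", "\n")

flagged <- unique(scr[scr$flagged, c("parameter", "covariate", "test")])
flagged <- flagged[!(flagged$covariate %in% vif$excluded), ]
cand <- lapply(seq_len(nrow(flagged)), function(j)
  covariate_link(flagged$parameter[j], flagged$covariate[j],
                 kind = if (flagged$test[j] == "anova") "categorical"
                 else "continuous",
                 ref = if (flagged$test[j] == "anova") 0 else NA))

if (length(cand)) {
  res <- stepwise_search(fit, cand, dataset,
                         settings = saem_settings(k1 = 60, k2 = 30),
                         n_is = 300, screening = scr, seed = 422)
  write.csv(res$trace, "results/covsearch_trace.csv", row.names = FALSE)
  cat("selected links:\n")
  for (l in res$model$links)
    cat(sprintf("  %s on %s: beta = %.3g\n", l$covariate, l$parameter,
                l$beta))
  if (length(res$model$links)) {
    wt <- wald_tests(res$fit)
    write.csv(wt, "results/wald_tests.csv", row.names = FALSE)
    print(wt)
  }
} else cat("no candidates passed screening\n")
cat("written: results/screening.csv, covsearch_trace.csv\n")
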