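#!/usr/bin/env Rscript
# Stage 7 — covariate-effect summaries.
# Geometric-mean PK parameters by gender, BSA and weight subgroups
# (healthy adults), and terminal-phase mean log-concentration curves per
# subgroup; health-status contrast restricted to American subjects.

library(salbupk)
dir.create("results", showWarnings = FALSE)

cohort <- read.csv("results/cohort.csv")
dataset <- read_pk_dataset("results/dataset.csv")
init <- init_from_nca(dataset)
fit <- saem_fit(dataset, init = init,
                settings = saem_settings(k1 = 150, k2 = 80), seed = 421)
ebes <- compute_ebes(fit, quiet = TRUE)
covtab <- do.call(rbind, lapply(fit$data, function(s) s$cov))

adult_healthy <- cohort$age >= 20 & cohort$health_status == "healthy"
cat(sum(adult_healthy), "healthy adults in the stratified analysis\n")

sg <- rbind(
  summarize_subgroups(ebes$params, covtab, list(covariate = "SEX"),
                      parameters = c("Mtt", "Cl"), filter = adult_healthy),
  summarize_subgroups(ebes$params, covtab,
                      list(covariate = "BSA",
                           breaks = c(0.9, 1.6, 2.4)),
                      parameters = c("V1", "Cl"), filter = adult_healthy),
  summarize_subgroups(ebes$params, covtab,
                      list(covariate = "WT", breaks = c(25, 75, 110)),
                      parameters = c("V1", "Cl"), filter = adult_healthy))
write.csv(sg, "results/subgroup_geometric_means.csv", row.names = FALSE)
print(transform(sg, geometric_mean = signif(geometric_mean, 3),
                geometric_sd = signif(geometric_sd, 3)))

grp <- data.frame(ID = cohort$id,
                  group = ifelse(cohort$gender == "female", "female", "male"))
keep <- cohort$id[adult_healthy]
tc_sex <- terminal_phase_curves(dataset[dataset$ID %in% keep, ],
                                grp[grp$ID %in% keep, ], c(18, 24))
write.csv(tc_sex, "results/terminal_phase_by_gender.csv", row.names = FALSE)

amer <- cohort$id[cohort$race == "american" & cohort$age >= 20]
grp_h <- data.frame(ID = cohort$id, group = cohort$health_status)
tc_h <- terminal_phase_curves(dataset[dataset$ID %in% amer, ],
                              grp_h[grp_h$ID %in% amer, ], c(18, 24))
write.csv(tc_h, "results/terminal_phase_by_health.csv", row.names = FALSE)
cat("written: results/subgroup_geometric_means.csv, terminal_phase_*.csv\n")
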