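#!/usr/bin/env Rscript
# Stage 1 — virtual population.
# Builds the 40-subject cohort used throughout: 20 American (6 healthy,
# 4 obese, 10 cirrhosis A), 10 Asian and 10 Chinese healthy subjects,
# ages 5-65, 60% male, BMI classes on the standard adult scale.

library(salbupk)
dir.create("results", showWarnings = FALSE)

cohort <- sample_cohort(default_cohort_spec(seed = 2024))
write.csv(cohort, "results/cohort.csv", row.names = FALSE)

cat("Cohort of", nrow(cohort), "subjects\n")
cat(sprintf("  females/males: %d/%d\n", sum(cohort$gender == "female"),
            sum(cohort$gender == "male")))
cat(sprintf("  age    %.1f +/- %.1f years\n", mean(cohort$age), sd(cohort$age)))
cat(sprintf("  weight %.1f +/- %.1f kg (range %.1f-%.1f)\n",
            mean(cohort$weight), sd(cohort$weight),
            min(cohort$weight), max(cohort$weight)))
cat(sprintf("  BSA    %.2f +/- %.2f m^2 (range %.2f-%.2f)\n",
            mean(cohort$bsa), sd(cohort$bsa), min(cohort$bsa),
            max(cohort$bsa)))
print(table(cohort$race, cohort$health_status))
cat("written: results/cohort.csv\n")
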