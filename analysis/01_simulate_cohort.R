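#!/usr/bin/env Rscript
# Step 1: simulate the study-scale synthetic EHR cohort.
#
# The cohort emulates a mid-size single-centre diabetes extract: two
# correlated feature blocks (comorbidities, risk factors), 256
# independent diagnosis/medication-style noise columns, 5 redundant
# near-duplicates, demographics, and a logistic type-2-diabetes-like
# outcome at roughly 20% prevalence. Curated downstream it yields an
# 8,482-record by 286-variable binary matrix.

library(ehrnet)

seed <- 20190927
dir.create("results", showWarnings = FALSE)

spec <- study_cohort_spec(seed = seed)
gc <- generate_cohort(spec)
write_cohort(gc$table, "results/cohort.csv")

cat("Simulated cohort:", nrow(gc$table$data), "records x",
    ncol(gc$table$data), "variables\n")
cat("Outcome prevalence:", round(mean(gc$table$data$outcome), 3), "\n")
cat("Planted predictive variables:",
    paste(gc$truth$predictive_set, collapse = ", "), "\n")
cat("Wrote results/cohort.csv (+ cohort.meta.csv)\n")
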