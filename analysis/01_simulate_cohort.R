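#!/usr/bin/env Rscript
# Stage 1: generate the synthetic screening cohort at the study scale and
# write its tables (maternal, scans, outcomes) under results/cohort/.
#
# The generator emulates a nulliparous cohort with ~9% SGA prevalence, a
# latent growth-restricted subgroup with decelerating abdominal growth,
# research scans at ~20/28/36 weeks, and clinically indicated scans selected
# by an indication model correlated with fetal smallness.

library(growthscreen)

seed <- 20260101L
params <- cohort_params(seed = seed)
cohort <- generate_cohort(params)

dir.create("results", showWarnings = FALSE)
write_cohort(cohort, "results/cohort")
utils::write.csv(truth_table(cohort), "results/cohort/truth_synthetic.csv",
                 row.names = FALSE)

tr <- truth_table(cohort)
message(sprintf("cohort: %d pregnancies, %d scans", nrow(cohort$outcomes),
                nrow(cohort$scans)))
message(sprintf("latent FGR class: %.1f%%; selectively scanned: %.1f%%",
                100 * mean(tr$fgr_class), 100 * mean(tr$scanned_selective)))
message(sprintf("term deliveries (>=37wk): %.1f%%",
                100 * mean(cohort$outcomes$ga_delivery_weeks >= 37)))
message("written: results/cohort/{maternal,scans,outcomes,truth_synthetic}.csv")
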