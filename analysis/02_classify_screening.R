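#!/usr/bin/env Rscript
# Stage 2: classify the cohort -- EFW percentiles per screening policy,
# gold-standard SGA from birthweight, composite outcome flags, GA-adjusted
# Z-scores, abdominal-circumference growth velocity, and the five
# growth-restriction marker decile flags.

library(growthscreen)

tabs <- read_cohort("results/cohort")
val <- validate_cohort(tabs$scans, tabs$outcomes, tabs$maternal)
stopifnot(attr(val, "ok"))

cls <- classify_cohort(tabs$scans, tabs$outcomes, tabs$maternal)
utils::write.csv(cls, "results/classification.csv", row.names = FALSE)

message(sprintf("classified %d pregnancies", nrow(cls)))
message(sprintf("SGA (birthweight <10th): %d (%.1f%%); severe SGA: %d (%.1f%%)",
                sum(cls$sga), 100 * mean(cls$sga),
                sum(cls$severe_sga), 100 * mean(cls$severe_sga)))
message(sprintf("screen positive -- universal: %d (%.1f%%), selective: %d (%.1f%%)",
                sum(cls$universal_status == "positive"),
                100 * mean(cls$universal_status == "positive"),
                sum(cls$selective_status == "positive"),
                100 * mean(cls$selective_status == "positive")))
message(sprintf("composite neonatal morbidity: %.1f%%",
                100 * mean(cls$neonatal_morbidity)))
message("written: results/classification.csv")
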