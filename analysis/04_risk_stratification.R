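#!/usr/bin/env Rscript
# Stage 4: stratified relative risks of perinatal outcomes for screen-
# positive pregnancies, overall and split by abdominal-circumference growth
# velocity, plus the marker-by-marker interaction analysis (the association
# between a positive screen and morbidity within the normal vs abnormal
# stratum of each growth-restriction marker).

library(growthscreen)

cls <- utils::read.csv("results/classification.csv")

risk <- table4_report(cls)
utils::write.csv(risk, "results/table_risk_stratification.csv",
                 row.names = FALSE)
markers <- marker_strata_report(cls)
utils::write.csv(markers, "results/table_marker_strata.csv", row.names = FALSE)

show <- subset(risk, outcome == "neonatal_morbidity")
message("relative risk of neonatal morbidity (reference: EFW >= 10th pct):")
for (i in seq_len(nrow(show)))
  message(sprintf("  %-24s RR %.2f (%.2f-%.2f), Fisher p = %.3g [%d/%d exposed]",
                  show$exposure[i], show$rr[i], show$lower[i], show$upper[i],
                  show$p[i], show$events_exposed[i], show$n_exposed[i]))

acgv <- markers[markers$marker == "acgv_bottom_decile", ]
message(sprintf(
  "ACGV interaction: RR %.2f (normal velocity) vs %.2f (lowest decile), p = %.3g (logistic cross-check p = %.3g)",
  acgv$rr_normal, acgv$rr_abnormal, acgv$p_interaction,
  acgv$p_interaction_logistic))
message("written: results/table_risk_stratification.csv, results/table_marker_strata.csv")
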