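#!/usr/bin/env Rscript
# Stage 3: paired diagnostic-accuracy comparison of selective vs universal
# screening against the SGA and severe-SGA gold standards: screening counts,
# the formatted effectiveness table (sensitivity through likelihood ratios,
# relative sensitivity with McNemar p), predictive-value and LR comparison
# tests, and ROC AUC of the universal EFW percentile.

library(growthscreen)

cls <- utils::read.csv("results/classification.csv")

counts <- screening_counts(cls)
utils::write.csv(counts, "results/table_screening_counts.csv", row.names = FALSE)

psd <- paired_screen_data(cls$selective_status, cls$universal_status, cls$sga)
psd_sev <- paired_screen_data(cls$selective_status, cls$universal_status,
                              cls$severe_sga)
acc <- accuracy_report(psd)
acc_sev <- accuracy_report(psd_sev)
utils::write.csv(acc, "results/table_accuracy_sga.csv", row.names = FALSE)
utils::write.csv(acc_sev, "results/table_accuracy_severe_sga.csv",
                 row.names = FALSE)

message("diagnostic effectiveness (SGA):")
for (i in seq_len(nrow(acc)))
  message(sprintf("  %-22s selective %-18s universal %s",
                  acc$metric[i], acc$selective[i], acc$universal[i]))

rs <- relative_sensitivity(psd)
message(sprintf("relative sensitivity %.2f (%.2f-%.2f), McNemar p = %.2g",
                rs$ratio, rs$lower, rs$upper, rs$p_mcnemar))
pv <- predictive_value_test(psd, "ppv", B = 2000, seed = 1)
message(sprintf("PPV comparison: score p = %.2g (bootstrap %.2g)",
                pv$p, pv$p_boot))
lr <- likelihood_ratio_test(psd, "pos", B = 2000, seed = 1)
message(sprintf("LR+ comparison: p = %.2g (bootstrap %.2g)", lr$p, lr$p_boot))
auc <- roc_auc(-cls$universal_efw_percentile, cls$sga)
message(sprintf("universal screening AUC for SGA: %.3f (%.3f-%.3f)",
                auc$auc, auc$lower, auc$upper))
message("written: results/table_screening_counts.csv, results/table_accuracy_*.csv")
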