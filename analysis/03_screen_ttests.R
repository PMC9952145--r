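#!/usr/bin/env Rscript
# Welch t-test screen of every subject-level feature, healthy vs pooled
# CVD, at alpha = 0.05 (uncorrected, with a Benjamini-Hochberg column for
# honest reading).

library(ppgscreen)

sf <- read.csv("results/subject_features.csv")
tt <- ttest_features(sf)
render_reports(ttest_results = tt, out_dir = "results/reports")

cat(sum(tt$significant), "of", nrow(tt),
    "features differ significantly (p < 0.05) between healthy and CVD.\n")
cat("Top ten by p-value:\n")
print(tt[1:10, c("feature", "t_statistic", "p_value", "mean_healthy",
                 "mean_cvd")], digits = 3, row.names = FALSE)
cat("After BH correction:", sum(tt$p_bh < 0.05), "remain significant.\n")
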