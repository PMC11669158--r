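#!/usr/bin/env Rscript
# Step 3: group statistics of the simulated assay, as conventionally
# reported: per-strain mean +/- SD of the nine coverage values, one-way
# ANOVA, and Holm-Sidak multiple comparisons of every strain versus the
# chassis control.
#
# Reads results/coverage.csv; writes results/group_summary.csv and
# results/comparisons.csv.

library(hyphacover)

res <- utils::read.csv("results/coverage.csv")
tab <- data.frame(strain = res$strain,
                  value = res$percent_hyphae_covered,
                  replicate = res$replicate)

summ <- group_summary(tab)
utils::write.csv(summ, "results/group_summary.csv", row.names = FALSE)
message("per-strain coverage, mean +/- SD over 9 images:")
for (i in seq_len(nrow(summ)))
  message(sprintf("  %-8s %.2f +/- %.2f (n = %d)", summ$strain[i],
                  summ$mean[i], summ$sd[i], summ$n[i]))

fit <- one_way_anova(tab)
message(sprintf("one-way ANOVA: F(%d, %d) = %.2f, p = %.3g",
                fit$df_between, fit$df_within, fit$F, fit$p))

cmp <- holm_sidak_vs_control(tab, control = "control")
utils::write.csv(cmp, "results/comparisons.csv", row.names = FALSE)
message("Holm-Sidak comparisons versus control:")
for (i in seq_len(nrow(cmp)))
  message(sprintf("  %-8s t = %6.2f  adj. p = %.2e  %s", cmp$strain[i],
                  cmp$t_statistic[i], cmp$adjusted_p[i],
                  cmp$significance_tier[i]))
message("wrote results/group_summary.csv and results/comparisons.csv")
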