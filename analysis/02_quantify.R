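#!/usr/bin/env Rscript
# Step 2: run the two-channel segmentation and coverage pipeline over the
# simulated assay, then compare the per-image estimates with the
# generator's ground truth.
#
# Reads scratch/benchmark/manifest.csv (written by 01_simulate.R); writes
# results/coverage.csv (one row per field of view) and
# results/recovery.csv (estimate vs truth).

library(hyphacover)

man <- read_manifest("scratch/benchmark/manifest.csv")
message("processing ", nrow(man), " fields of view ...")
res <- run_batch(man, pipeline_config(), verbose = TRUE)

write_results_table(res[res$status == "ok", ], "results/coverage.csv")

truth <- utils::read.csv("results/truth.csv")
rec <- merge(res[res$status == "ok",
                 c("id", "strain", "percent_hyphae_covered")],
             truth[, c("id", "truth_percent_covered")], by = "id")
utils::write.csv(rec, "results/recovery.csv", row.names = FALSE)

message(sprintf("estimate vs truth: MAE = %.2f pp, Spearman rho = %.3f",
                mean(abs(rec$percent_hyphae_covered -
                           rec$truth_percent_covered)),
                cor(rec$percent_hyphae_covered, rec$truth_percent_covered,
                    method = "spearman")))
message("per-strain mean estimated coverage (%):")
agg <- aggregate(percent_hyphae_covered ~ strain, res[res$status == "ok", ],
                 mean)
for (i in seq_len(nrow(agg)))
  message(sprintf("  %-8s %.2f", agg$strain[i],
                  agg$percent_hyphae_covered[i]))
message("wrote results/coverage.csv and results/recovery.csv")
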