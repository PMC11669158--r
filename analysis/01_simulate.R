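#!/usr/bin/env Rscript
# Step 1: simulate a synthetic binding assay.
#
# Emulates the acquisition design of the hyphae binding assay: six
# bacterial strains (two adhesive, one chassis control, three
# non-adhesive construct controls), imaged at 3 random slide positions on
# each of 3 days — nine two-channel fields of view per strain. Adhesive
# strains carry rods centered on the filaments; non-adhesive strains only
# carry rods placed clear of them, so their ground-truth coverage is
# exactly zero.
#
# Images (TIFF) go to scratch/benchmark/ (binary artifacts); the manifest
# and ground-truth tables are copied to results/.

library(hyphacover)

out_img <- "scratch/benchmark"
out_res <- "results"
dir.create(out_res, recursive = TRUE, showWarnings = FALSE)

conditions <- data.frame(
  strain         = c("control", "act", "dec", "SP2", "chi", "SP1"),
  n_bacteria_on  = c(0, 0, 0, 0, 9, 9),   # ~2.5% truth coverage for binders
  n_bacteria_off = c(20, 20, 20, 20, 20, 20)
)

message("simulating ", nrow(conditions), " strains x 9 fields of view ...")
bench <- generate_benchmark(out_img, conditions,
                            replicates = 3, positions = 3,
                            base_params = synthetic_params(),
                            seed = 20260925 %% 10000)

file.copy(bench$manifest_path, file.path(out_res, "manifest.csv"),
          overwrite = TRUE)
file.copy(bench$truth_path, file.path(out_res, "truth.csv"),
          overwrite = TRUE)

truth <- bench$truth
agg <- aggregate(truth_percent_covered ~ strain, truth, mean)
message("mean ground-truth coverage per strain (%):")
for (i in seq_len(nrow(agg)))
  message(sprintf("  %-8s %.2f", agg$strain[i], agg$truth_percent_covered[i]))
message("images in ", out_img, "; manifest and truth tables in ", out_res)
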