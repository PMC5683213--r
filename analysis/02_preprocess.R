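#!/usr/bin/env Rscript
# Step 2 — frozen preprocessing tracks.
#
# ATR track: restrict to 1900-700 cm-1 and baseline-offset correct (liquid
# spectra are reproducible enough that nothing more is needed).
# HTS track: restrict to 1900-700 cm-1, Savitzky-Golay second derivative
# (window 15 points, polynomial order 2) to cancel film-thickness offsets
# and slopes, then average the 3 technical replicates -> 222 spectra.

suppressPackageStartupMessages(library(fermspec))

seed <- 1L
dir.create("scratch/data", recursive = TRUE, showWarnings = FALSE)
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

summary_rows <- list()
for (mode in c("ATR", "HTS")) {
  bm <- benchmark_dataset(mode, seed = if (mode == "HTS") seed else seed + 1000L)
  plan <- preprocess_plan(if (mode == "ATR") "atr_media" else "hts_media")
  print(plan)
  pp <- apply_plan(bm$dataset, plan)
  out_file <- sprintf("scratch/data/preprocessed_%s.csv", tolower(mode))
  write_spectra_csv(pp, out_file)
  summary_rows[[mode]] <- data.frame(
    mode = mode, plan = plan$name,
    spectra_in = n_spectra(bm$dataset), spectra_out = n_spectra(pp),
    points_out = length(pp$grid),
    region = sprintf("%g-%g", max(pp$grid), min(pp$grid)))
  write_run_manifest(sprintf("results/tables/manifest_preprocess_%s.json",
                             tolower(mode)),
                     config = list(step = "preprocess", plan = plan$name),
                     seed = if (mode == "HTS") seed else seed + 1000L,
                     outputs = out_file)
}
summary_tab <- do.call(rbind, summary_rows)
write.csv(summary_tab, "results/tables/preprocess_summary.csv",
          row.names = FALSE)
print(summary_tab, row.names = FALSE)
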