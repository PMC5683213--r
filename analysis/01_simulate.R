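#!/usr/bin/env Rscript
# Step 1 — simulate the screening study.
#
# Generates the seeded synthetic datasets emulating the fermentation
# screening: 3 strains x 2 temperatures x 12 days x 3 wells of supernatant
# (648 spectra) plus 6 starting growth media (18 spectra), in both ATR
# (liquid, water-dominated) and HTS (10x-diluted dry film) modes.  Small
# tables (reference concentrations, design summary) go to results/; the
# full spectra matrices are bulky and land in scratch/ as wide CSV.

suppressPackageStartupMessages(library(fermspec))

seed <- 1L
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
dir.create("scratch/data", recursive = TRUE, showWarnings = FALSE)

profiles <- benchmark_profiles()
write.csv(profiles, "results/tables/fermentation_profiles.csv",
          row.names = FALSE)
cat(sprintf("Fermentation profiles: glucose %.0f -> %.1f g/L; producer plateau %.1f (20C) / %.1f (30C) g/L\n",
            max(profiles$glucose), min(profiles$glucose),
            max(profiles$citric_acid[profiles$temperature == 20]),
            max(profiles$citric_acid[profiles$temperature == 30])))

for (mode in c("ATR", "HTS")) {
  bm <- benchmark_dataset(mode, seed = if (mode == "HTS") seed else seed + 1000L)
  cat(sprintf("%s: %d spectra x %d wavenumbers\n", mode,
              n_spectra(bm$dataset), length(bm$dataset$grid)))
  spectra_file <- sprintf("scratch/data/spectra_%s.csv", tolower(mode))
  write_spectra_csv(bm$dataset, spectra_file)
  write.csv(bm$dataset$metadata,
            sprintf("scratch/data/metadata_%s.csv", tolower(mode)),
            row.names = FALSE)
  write.csv(bm$reference,
            sprintf("results/tables/reference_%s.csv", tolower(mode)),
            row.names = FALSE)
  write_run_manifest(sprintf("results/tables/manifest_simulate_%s.json",
                             tolower(mode)),
                     config = list(step = "simulate", mode = mode),
                     seed = if (mode == "HTS") seed else seed + 1000L,
                     outputs = c(spectra_file,
                                 sprintf("results/tables/reference_%s.csv",
                                         tolower(mode))))
}
cat("Done: spectra in scratch/data, reference tables in results/tables\n")
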