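# Small in-code fixtures shared across test files.

# a tiny dataset with known values on a uniform grid
tiny_dataset <- function(values, grid = seq(700, 700 + 2 * (ncol(values) - 1), 2)) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  spectral_dataset(grid, values,
                   data.frame(sample_id = sprintf("s%02d", seq_len(nrow(values)))))
}

# noiseless two-component Beer-Lambert mixtures on a small grid
mixture_dataset <- function(conc_a, conc_b, grid = seq(900, 1800, 5)) {
  sa <- build_pure_spectrum(band(1035, 35, 0.5), grid)
  sb <- build_pure_spectrum(band(1725, 40, 0.5), grid)
  X <- outer(conc_a, sa) + outer(conc_b, sb)
  spectral_dataset(grid, X,
                   data.frame(sample_id = sprintf("mix%02d", seq_along(conc_a))))
}

# quiet acquisition: deterministic spectra (no jitter, drift or noise)
quiet_acq <- function(mode = "HTS", ...) {
  acquisition_config(mode, pathlength_jitter_sd = 0,
                     baseline_drift_amplitude = 0, noise_sd = 0, ...)
}

# single-condition design for focused synthesis tests
mini_design <- function(strain = "P_glabrum", temperature = 30, days = 2,
                        technical_replicates = 3) {
  d <- screening_design(technical_replicates = technical_replicates,
                        strains = strain, temperatures = temperature,
                        days = days, wells = 1)
  d
}
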