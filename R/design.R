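#' Sampling design of the emulated high-throughput screening study
#'
#' Builds the per-spectrum metadata skeleton of the microtiter-plate
#' screening design: 3 strains x 2 temperatures (20, 30 C) x 12 sampling
#' days x 3 biological wells of fermentation supernatant, plus 6 starting
#' growth-medium samples (3 per temperature, day 0), each measured in
#' `technical_replicates` technical replicates.  With the default 3
#' replicates this yields 216 supernatant and 6 medium samples, i.e. 648 and
#' 18 spectra.
#'
#' Optionally the biomass arm is included: the same supernatant layout minus
#' the two strain x temperature conditions that could not be sampled on day
#' 1 for lack of growth (the U. isabellina- and P. glabrum-type strains at
#' 20 C), giving 210 samples / 630 spectra.
#'
#' @param technical_replicates technical replicates per sample (>= 1).
#' @param include_biomass also emit the biomass sampling rows?
#' @param strains strain labels (order defines well layout).
#' @param temperatures cultivation temperatures (degrees C).
#' @param days number of cultivation days.
#' @param wells biological well replicates per condition.
#' @return data frame with columns `spectrum_id`, `sample_id`, `strain`
#'   (`NA` for growth media), `temperature`, `day` (0 for media),
#'   `well_replicate`, `technical_replicate`, `sample_type`
#'   (`medium`/`supernatant`/`biomass`).
#' @examples
#' d <- screening_design()
#' table(d$sample_type) / 3            # samples per type
#' @export
screening_design <- function(technical_replicates = 3,
                             include_biomass = FALSE,
                             strains = c("M_circinelloides",
                                         "U_isabellina", "P_glabrum"),
                             temperatures = c(20, 30),
                             days = 12, wells = 3) {
  stopifnot(technical_replicates >= 1, days >= 1, wells >= 1)
  sup <- expand.grid(strain = strains, temperature = temperatures,
                     day = seq_len(days), well_replicate = seq_len(wells),
                     technical_replicate = seq_len(technical_replicates),
                     stringsAsFactors = FALSE)
  sup$sample_type <- "supernatant"
  med <- expand.grid(strain = NA_character_, temperature = temperatures,
                     day = 0L, well_replicate = seq_len(wells),
                     technical_replicate = seq_len(technical_replicates),
                     stringsAsFactors = FALSE)
  med$sample_type <- "medium"
  out <- rbind(med, sup)
  if (include_biomass) {
    bio <- sup
    bio$sample_type <- "biomass"
    # insufficient growth on day 1 for two of the 20 C conditions
    skip <- bio$day == 1 & bio$temperature == 20 &
      bio$strain %in% strains[2:3]
    out <- rbind(out, bio[!skip, ])
  }
  out$sample_id <- ifelse(
    out$sample_type == "medium",
    sprintf("med_%dC_w%d", out$temperature, out$well_replicate),
    sprintf("%s_%s_%dC_d%02d_w%d",
            substr(out$sample_type, 1, 3), out$strain, out$temperature,
            out$day, out$well_replicate))
  out$spectrum_id <- sprintf("%s_r%d", out$sample_id, out$technical_replicate)
  ord <- order(out$sample_type, out$strain, out$temperature, out$day,
               out$well_replicate, out$technical_replicate)
  out <- out[ord, c("spectrum_id", "sample_id", "strain", "temperature",
                    "day", "well_replicate", "technical_replicate",
                    "sample_type")]
  rownames(out) <- NULL
  stopifnot(!anyDuplicated(out$spectrum_id))
  out
}
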