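#' Acquisition model configuration
#'
#' Describes how a spectrum of a liquid sample is turned into a recorded
#' absorbance trace.  Two modes mirror the two FTIR sampling techniques used
#' for fermentation supernatants:
#'
#' * **ATR** — the liquid measured directly on the crystal: no dilution, a
#'   well-controlled optical path (no pathlength jitter), and strong water
#'   bands superimposed at fixed weight;
#' * **HTS** — 10x diluted samples dried to films on a silicon microplate:
#'   water-free, but with a per-spectrum multiplicative pathlength factor
#'   (mean 1, sd `pathlength_jitter_sd`) reflecting irreproducible film
#'   formation.
#'
#' Both modes add a random low-order (quadratic) baseline drift bounded by
#' `baseline_drift_amplitude` and white noise of sd `noise_sd`.  The default
#' grid is 4000-500 cm-1 at 2 cm-1 spacing — finer than a 6 cm-1 instrument
#' resolution so that 30-40 cm-1 wide bands are well sampled.
#'
#' @param mode `"ATR"` or `"HTS"`.
#' @param grid_start,grid_end grid limits (cm-1); may be given in
#'   descending presentation order, stored ascending.
#' @param grid_spacing grid step (cm-1), > 0.
#' @param dilution_factor sample dilution before measurement.
#' @param pathlength_jitter_sd relative sd of the per-spectrum
#'   multiplicative pathlength factor.
#' @param baseline_drift_amplitude bound (AU) on each random baseline
#'   coefficient.
#' @param noise_sd white-noise sd (AU).
#' @param include_water superimpose the water component at fixed weight?
#' @param water_weight weight of the water component when included.
#' @param technical_replicates spectra recorded per sample (>= 1).
#' @param seed integer seed making the synthesis deterministic.
#' @return object of class `acquisition_config` (a list of the above).
#' @export
acquisition_config <- function(mode = c("HTS", "ATR"),
                               grid_start = 4000, grid_end = 500,
                               grid_spacing = 2,
                               dilution_factor = if (mode == "HTS") 10 else 1,
                               pathlength_jitter_sd = if (mode == "HTS") 0.10 else 0,
                               baseline_drift_amplitude = 1e-3,
                               noise_sd = 1e-4,
                               include_water = mode == "ATR",
                               water_weight = 1,
                               technical_replicates = 3,
                               seed = 1L) {
  mode <- match.arg(mode)
  if (grid_spacing <= 0) stop("grid_spacing must be > 0", call. = FALSE)
  if (technical_replicates < 1) stop("technical_replicates must be >= 1", call. = FALSE)
  if (dilution_factor <= 0) stop("dilution_factor must be > 0", call. = FALSE)
  if (pathlength_jitter_sd < 0 || noise_sd < 0 || baseline_drift_amplitude < 0) {
    stop("noise parameters must be >= 0", call. = FALSE)
  }
  lo <- min(grid_start, grid_end)
  hi <- max(grid_start, grid_end)
  structure(list(mode = mode,
                 grid = seq(lo, hi, by = grid_spacing),
                 dilution_factor = dilution_factor,
                 pathlength_jitter_sd = pathlength_jitter_sd,
                 baseline_drift_amplitude = baseline_drift_amplitude,
                 noise_sd = noise_sd,
                 include_water = include_water,
                 water_weight = water_weight,
                 technical_replicates = technical_replicates,
                 seed = as.integer(seed)),
            class = "acquisition_config")
}

#' Synthesize an FTIR dataset from a design, profiles and a band library
#'
#' Implements the Beer-Lambert mixing model: for spectrum i of a sample with
#' component concentrations c (g/L),
#' \deqn{A_i(\nu) = m_i \sum_c \frac{c}{d \cdot c_{ref}} s_c(\nu) + b_i(\nu) + \varepsilon_i(\nu)}
#' where `s_c` are the pure-component spectra of the library (heights
#' defined at `c_ref`), `d` the dilution factor, `m_i` a per-spectrum
#' multiplicative pathlength factor, `b_i` a random quadratic baseline and
#' `eps_i` white noise.  In ATR mode the water component (scaled by `m_i`)
#' is superimposed at fixed weight and the dilution is 1.  A fixed
#' background component (weight 1 at reference concentration, before
#' dilution) stands in for the non-tracked medium constituents.
#'
#' The reference-concentration table records the true (pre-dilution,
#' noise-free) analyte concentrations per sample.  Given the same seed the
#' output is bit-identical.
#'
#' @param design per-spectrum metadata from [screening_design()] (medium
#'   and supernatant rows only).
#' @param profiles fermentation profiles covering every
#'   (strain, temperature, day) in the design, e.g. [benchmark_profiles()].
#' @param library a [component_library()]; must contain `glucose`,
#'   `citric_acid` and `background` (plus `water` in ATR mode).
#' @param acq an [acquisition_config()].
#' @return list with elements `dataset` (a [spectral_dataset()]) and
#'   `reference` (data frame `sample_id`, `glucose`, `citric_acid` in g/L).
#' @export
synthesize_dataset <- function(design, profiles,
                               library = default_component_library(),
                               acq = acquisition_config("HTS")) {
  stopifnot(inherits(acq, "acquisition_config"),
            inherits(library, "component_library"))
  needed <- c("glucose", "citric_acid", "background",
              if (acq$include_water) "water")
  missing_c <- setdiff(needed, names(library$components))
  if (length(missing_c)) {
    stop("component(s) missing from library: ",
         paste(missing_c, collapse = ", "), call. = FALSE)
  }
  if (any(design$sample_type == "biomass")) {
    stop("biomass spectra are not synthesized; drop biomass rows from the design",
         call. = FALSE)
  }

  # map each spectrum to its true concentrations
  conc <- concentrations_for_design(design, profiles)

  grid <- acq$grid
  p <- length(grid)
  n <- nrow(design)
  ref_c <- library$reference_concentration
  s_glc <- build_pure_spectrum(library$components$glucose, grid)
  s_cit <- build_pure_spectrum(library$components$citric_acid, grid)
  s_bg <- build_pure_spectrum(library$components$background, grid)
  scale <- 1 / (acq$dilution_factor * ref_c)
  mix <- outer(conc$glucose * scale, s_glc) +
    outer(conc$citric_acid * scale, s_cit)
  mix <- mix + matrix(rep(s_bg / acq$dilution_factor, each = n), nrow = n)
  if (acq$include_water) {
    s_w <- build_pure_spectrum(library$components$water, grid)
    mix <- mix + matrix(rep(acq$water_weight * s_w, each = n), nrow = n)
  }

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(acq$seed)
  m <- 1 + stats::rnorm(n, 0, acq$pathlength_jitter_sd)
  # random quadratic drift: coefficients bounded so |b(nu)| <= amplitude
  u <- 2 * (grid - min(grid)) / (max(grid) - min(grid)) - 1
  amp <- acq$baseline_drift_amplitude / 3
  bc <- matrix(stats::runif(3 * n, -amp, amp), nrow = n)
  drift <- bc %*% rbind(rep(1, p), u, u^2)
  eps <- matrix(stats::rnorm(n * p, 0, acq$noise_sd), nrow = n)
  absorbance <- mix * m + drift + eps

  ds <- spectral_dataset(grid, absorbance, design)
  ref <- unique(data.frame(sample_id = design$sample_id,
                           glucose = conc$glucose,
                           citric_acid = conc$citric_acid,
                           stringsAsFactors = FALSE))
  rownames(ref) <- NULL
  list(dataset = ds, reference = ref)
}

concentrations_for_design <- function(design, profiles) {
  glc <- numeric(nrow(design))
  cit <- numeric(nrow(design))
  is_med <- design$sample_type == "medium"
  if (any(is_med)) {
    d0 <- profiles[profiles$day == 0, ]
    for (temp in unique(design$temperature[is_med])) {
      rows <- d0[d0$temperature == temp, ]
      if (nrow(rows) == 0L) {
        stop("profiles lack day-0 composition for temperature ", temp,
             call. = FALSE)
      }
      sel <- is_med & design$temperature == temp
      glc[sel] <- mean(rows$glucose)
      cit[sel] <- 0
    }
  }
  sup <- which(!is_med)
  if (length(sup)) {
    key_d <- paste(design$strain[sup], design$temperature[sup], design$day[sup])
    key_p <- paste(profiles$strain, profiles$temperature, profiles$day)
    hit <- match(key_d, key_p)
    if (anyNA(hit)) {
      stop("profiles do not cover condition(s): ",
           paste(unique(key_d[is.na(hit)]), collapse = "; "), call. = FALSE)
    }
    glc[sup] <- profiles$glucose[hit]
    cit[sup] <- profiles$citric_acid[hit]
  }
  data.frame(glucose = glc, citric_acid = cit)
}

#' Seeded benchmark dataset emulating the screening study
#'
#' Convenience wrapper combining [screening_design()],
#' [benchmark_profiles()], [default_component_library()] and
#' [synthesize_dataset()] with all defaults: 648 supernatant + 18 medium
#' spectra on the 4000-500 cm-1 grid, in either acquisition mode.
#'
#' @param mode `"HTS"` or `"ATR"`.
#' @param seed integer seed.
#' @return list with `dataset` and `reference`, as [synthesize_dataset()].
#' @export
benchmark_dataset <- function(mode = c("HTS", "ATR"), seed = 1L) {
  mode <- match.arg(mode)
  synthesize_dataset(screening_design(), benchmark_profiles(),
                     default_component_library(),
                     acquisition_config(mode, seed = seed))
}
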