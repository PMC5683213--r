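#' Simulate daily substrate and metabolite concentrations
#'
#' Generates a daily fermentation profile for one strain at one cultivation
#' temperature.  Glucose follows an exponential decay towards a residual
#' floor; citric acid, for producer strains, follows a logistic rise that
#' reaches (within ~1%) its plateau by `plateau_day` and stays there, which
#' is the qualitative shape observed for organic-acid producing fungi.
#' Non-producers secrete no acid.
#'
#' Concentrations are exact (deterministic); optional Gaussian measurement
#' noise emulating reference-analysis (HPLC) error can be added to support
#' robustness studies, in which case non-negativity is enforced by clamping.
#'
#' @param strain strain label.
#' @param temperature cultivation temperature (degrees C).
#' @param days number of cultivation days (>= 1); day 0 is the starting
#'   growth medium.
#' @param initial_glucose starting glucose concentration (g/L).
#' @param uptake_rate first-order glucose consumption rate (per day), >= 0.
#' @param glucose_floor residual glucose level (g/L) approached late in the
#'   cultivation.
#' @param producer logical; does this strain secrete citric acid?
#' @param acid_plateau citric-acid plateau concentration (g/L).
#' @param plateau_day day by which the plateau is effectively reached.
#' @param logistic_rate steepness of the logistic rise (per day); the
#'   default `9/plateau_day` places ~99% of the plateau at `plateau_day`.
#' @param reference_noise_sd sd (g/L) of additive noise on the reported
#'   concentrations (default 0 = exact).
#' @param seed RNG seed used only when `reference_noise_sd > 0`.
#' @return data frame with columns `strain`, `temperature`, `day`
#'   (0..days), `glucose`, `citric_acid` (g/L).
#' @examples
#' pr <- simulate_fermentation("P_glabrum", 20, producer = TRUE)
#' pr[pr$day %in% c(0, 6, 12), ]
#' @export
simulate_fermentation <- function(strain = "strain", temperature = 30,
                                  days = 12,
                                  initial_glucose = 80,
                                  uptake_rate = 0.4,
                                  glucose_floor = 7.5,
                                  producer = FALSE,
                                  acid_plateau = 7.5,
                                  plateau_day = 6,
                                  logistic_rate = 9 / plateau_day,
                                  reference_noise_sd = 0,
                                  seed = NULL) {
  vals <- c(days = days, initial_glucose = initial_glucose,
            uptake_rate = uptake_rate, glucose_floor = glucose_floor,
            acid_plateau = acid_plateau, plateau_day = plateau_day,
            logistic_rate = logistic_rate,
            reference_noise_sd = reference_noise_sd)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("kinetic parameters must be finite and non-negative", call. = FALSE)
  }
  if (days < 1) stop("days must be >= 1", call. = FALSE)
  if (glucose_floor > initial_glucose) {
    stop("glucose_floor cannot exceed initial_glucose", call. = FALSE)
  }
  t <- 0:days
  glucose <- glucose_floor + (initial_glucose - glucose_floor) *
    exp(-uptake_rate * t)
  if (producer) {
    mid <- plateau_day / 2
    f <- function(x) 1 / (1 + exp(-logistic_rate * (x - mid)))
    citric <- acid_plateau * (f(t) - f(0)) / (1 - f(0))
  } else {
    citric <- numeric(length(t))
  }
  if (reference_noise_sd > 0) {
    if (!is.null(seed)) {
      old <- get0(".Random.seed", envir = globalenv())
      on.exit(restore_rng(old), add = TRUE)
      set.seed(seed)
    }
    glucose <- pmax(0, glucose + stats::rnorm(length(t), 0, reference_noise_sd))
    citric <- pmax(0, citric + stats::rnorm(length(t), 0, reference_noise_sd))
    if (producer) citric[1] <- 0 else citric[] <- 0
  }
  data.frame(strain = strain, temperature = temperature, day = t,
             glucose = glucose, citric_acid = citric,
             stringsAsFactors = FALSE)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Reference fermentation profiles for the emulated screening study
#'
#' Three oleaginous filamentous fungi grown at 20 and 30 degrees C for 12
#' days on an 80 g/L glucose medium.  Only the *Penicillium glabrum*-type
#' strain produces citric acid, plateauing at about 7.5 g/L (20 C) and
#' 6.5 g/L (30 C) after 6 days.  Glucose uptake rates differ modestly
#' between strains and are slightly faster at 30 C, a realistic
#' between-condition spread that gives the calibration data its day and
#' temperature structure.
#'
#' @param temperatures temperatures (degrees C) to simulate.
#' @param days cultivation length in days.
#' @return data frame of stacked [simulate_fermentation()] outputs for all
#'   strain x temperature combinations.
#' @export
benchmark_profiles <- function(temperatures = c(20, 30), days = 12) {
  strains <- data.frame(
    strain = c("M_circinelloides", "U_isabellina", "P_glabrum"),
    uptake = c(0.35, 0.45, 0.40),
    producer = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(strains))) {
    for (temp in temperatures) {
      plateau <- if (temp >= 30) 6.5 else 7.5
      rate <- strains$uptake[i] * ifelse(temp >= 30, 1.15, 1)
      out[[length(out) + 1L]] <- simulate_fermentation(
        strain = strains$strain[i], temperature = temp, days = days,
        uptake_rate = rate, producer = strains$producer[i],
        acid_plateau = plateau)
    }
  }
  do.call(rbind, out)
}
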