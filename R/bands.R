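#' Define a vibrational band
#'
#' A band is parameterised by its center wavenumber, full width at half
#' maximum (FWHM) and peak absorbance at the library's reference
#' concentration.  Both Gaussian and Lorentzian profiles are supported; in
#' either case the profile value at the center equals `height` and the value
#' at `center +/- fwhm/2` equals `height/2`.
#'
#' @param center band position (cm-1).
#' @param fwhm full width at half maximum (cm-1), > 0.
#' @param height peak absorbance (AU) at the reference concentration, >= 0.
#' @param shape `"gaussian"` (default) or `"lorentzian"`.
#' @return one-row data frame with columns `center`, `fwhm`, `height`,
#'   `shape`; several bands are combined with `rbind()`.
#' @export
band <- function(center, fwhm, height, shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  if (!is.finite(fwhm) || fwhm <= 0) stop("fwhm must be > 0", call. = FALSE)
  if (!is.finite(height) || height < 0) stop("height must be >= 0", call. = FALSE)
  data.frame(center = center, fwhm = fwhm, height = height, shape = shape,
             stringsAsFactors = FALSE)
}

#' Evaluate a superposition of bands on a wavenumber grid
#'
#' Pure-component spectra are additive superpositions of their band
#' profiles.  Bands whose center falls outside the grid still contribute
#' whatever part of their tail overlaps the grid, with a warning.
#'
#' @param bands data frame of bands as produced by [band()] (possibly
#'   `rbind`-ed); an empty (zero-row) table yields an all-zero spectrum.
#' @param grid strictly monotone wavenumber vector (cm-1).
#' @return numeric vector of absorbance values, one per grid point.
#' @examples
#' g <- seq(900, 1200, 2)
#' s <- build_pure_spectrum(band(1035, 35, 1), g)
#' s[which.min(abs(g - 1035))]  # 1 at the band center
#' @export
build_pure_spectrum <- function(bands, grid) {
  grid <- as.numeric(grid)
  if (length(grid) == 0L) stop("grid must be non-empty", call. = FALSE)
  if (length(grid) > 1L && any(diff(grid) <= 0) && any(diff(grid) >= 0)) {
    stop("grid must be strictly monotone", call. = FALSE)
  }
  out <- numeric(length(grid))
  if (is.null(bands) || nrow(bands) == 0L) return(out)
  lo <- min(grid); hi <- max(grid)
  for (k in seq_len(nrow(bands))) {
    b <- bands[k, ]
    if (b$center < lo || b$center > hi) {
      warning(sprintf("band at %.1f cm-1 lies outside the grid (%.1f-%.1f); only its tail contributes",
                      b$center, lo, hi), call. = FALSE)
    }
    out <- out + band_profile(grid, b$center, b$fwhm, b$height, b$shape)
  }
  out
}

band_profile <- function(nu, center, fwhm, height, shape) {
  if (shape == "gaussian") {
    height * exp(-log(2) * (2 * (nu - center) / fwhm)^2)
  } else {
    hw2 <- (fwhm / 2)^2
    height * hw2 / ((nu - center)^2 + hw2)
  }
}

#' Default pure-component band library
#'
#' Band models for the species that dominate fermentation growth-medium
#' spectra in the mid infrared:
#'
#' * **glucose** — pyranose ring / C-O / C-OH bands concentrated in
#'   1200-900 cm-1 with the principal peak at 1035 cm-1 and FWHM of
#'   30-40 cm-1;
#' * **citric_acid** — the acid C=O stretch at 1725 cm-1 plus weaker C-O /
#'   C-OH / C-C bands in 1500-1000 cm-1;
#' * **water** — broad bands at 3300 (O-H stretch), 2110 (bend + libration
#'   combination), 1635 (HOH bend) and 580 cm-1 (libration), FWHM
#'   100-400 cm-1, dominating liquid-cell (ATR) spectra;
#' * **lipid** — C-H stretches (3050-2800), ester C=O (1745), CH2 bend
#'   (1460), C-O-C (1250-1070) and CH2 rock (720 cm-1);
#' * **background** — one broad lump standing in for yeast extract, salts
#'   and everything else in the medium.
#'
#' Heights are defined at the library's `reference_concentration`
#' (80 g/L, the starting glucose level of the emulated design) and scale
#' linearly with concentration under the Beer-Lambert mixing model; the
#' water and background components are used at fixed weight rather than
#' tracked concentrations.  Absolute AU values are a simulation convention
#' chosen so that undiluted 80 g/L glucose gives a ~0.5 AU peak at
#' 1035 cm-1.
#'
#' @return object of class `component_library`: list with `components`
#'   (named list of band tables), `molar_mass` (g/mol) and
#'   `reference_concentration` (g/L).
#' @export
default_component_library <- function() {
  glucose <- rbind(
    band(995, 40, 0.28),
    band(1035, 35, 0.50),
    band(1080, 30, 0.33),
    band(1150, 35, 0.18))
  citric <- rbind(
    band(1725, 40, 0.50),
    band(1400, 40, 0.18),
    band(1220, 40, 0.15),
    band(1140, 35, 0.10))
  water <- rbind(
    band(3300, 400, 1.20),
    band(2110, 250, 0.15),
    band(1635, 120, 0.85),
    band(580, 300, 0.55))
  lipid <- rbind(
    band(3010, 25, 0.10),
    band(2925, 40, 0.60),
    band(2855, 35, 0.35),
    band(1745, 30, 0.70),
    band(1460, 35, 0.20),
    band(1160, 60, 0.30),
    band(720, 20, 0.05))
  background <- rbind(
    band(1430, 900, 0.05),
    band(1585, 250, 0.04))
  component_library(
    components = list(glucose = glucose, citric_acid = citric,
                      water = water, lipid = lipid,
                      background = background),
    molar_mass = c(glucose = 180.16, citric_acid = 192.12,
                   water = 18.015, lipid = 885.4, background = 100),
    reference_concentration = 80)
}

#' Construct a component library
#'
#' @param components named list of band tables (see [band()]); every
#'   component must hold at least one band.
#' @param molar_mass named numeric vector (g/mol), positive, one entry per
#'   component.
#' @param reference_concentration concentration (g/L) at which the band
#'   heights are defined.
#' @return object of class `component_library`.
#' @export
component_library <- function(components, molar_mass, reference_concentration = 80) {
  stopifnot(is.list(components), length(components) > 0)
  if (is.null(names(components)) || any(names(components) == "")) {
    stop("components must be a named list", call. = FALSE)
  }
  for (nm in names(components)) {
    if (is.null(components[[nm]]) || nrow(components[[nm]]) == 0L) {
      stop("component '", nm, "' has no bands", call. = FALSE)
    }
  }
  if (!all(names(components) %in% names(molar_mass))) {
    stop("molar_mass must cover every component", call. = FALSE)
  }
  if (any(molar_mass <= 0)) stop("molar masses must be positive", call. = FALSE)
  if (reference_concentration <= 0) {
    stop("reference_concentration must be positive", call. = FALSE)
  }
  structure(list(components = components,
                 molar_mass = molar_mass,
                 reference_concentration = reference_concentration),
            class = "component_library")
}

#' @export
print.component_library <- function(x, ...) {
  cat("<component_library>", length(x$components), "components @ reference",
      x$reference_concentration, "g/L\n")
  for (nm in names(x$components)) {
    cat(sprintf("  %-12s %d bands, M = %.2f g/mol\n", nm,
                nrow(x$components[[nm]]), x$molar_mass[[nm]]))
  }
  invisible(x)
}
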