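#' Restrict a dataset to a spectral region
#'
#' Keeps the grid points inside the closed interval between `low` and
#' `high` (either order; 1900-700 cm-1 is the region holding the glucose
#' and citric-acid bands used for calibration).
#'
#' @param ds a [spectral_dataset()].
#' @param low,high region limits (cm-1), inclusive.
#' @return the restricted [spectral_dataset()].
#' @export
select_region <- function(ds, low = 1900, high = 700) {
  stopifnot(inherits(ds, "spectral_dataset"))
  lo <- min(low, high); hi <- max(low, high)
  keep <- ds$grid >= lo & ds$grid <= hi
  if (!any(keep)) {
    stop(sprintf("region %g-%g cm-1 does not intersect the grid (%g-%g)",
                 hi, lo, min(ds$grid), max(ds$grid)), call. = FALSE)
  }
  spectral_dataset(ds$grid[keep], ds$absorbance[, keep, drop = FALSE],
                   ds$metadata)
}

#' Baseline offset correction
#'
#' Subtracts from each spectrum its minimum over the current region, so the
#' per-spectrum minimum becomes exactly zero.  The minimal correction
#' appropriate for highly reproducible liquid-cell (ATR) measurements.
#'
#' @param ds a [spectral_dataset()].
#' @return the corrected [spectral_dataset()].
#' @export
baseline_offset <- function(ds) {
  stopifnot(inherits(ds, "spectral_dataset"))
  mins <- apply(ds$absorbance, 1, min)
  spectral_dataset(ds$grid, ds$absorbance - mins, ds$metadata)
}

#' Savitzky-Golay filter coefficients
#'
#' Closed-form convolution weights of the least-squares local polynomial
#' fit on `window` equispaced points: the returned weights, dotted with a
#' window of samples, give the fitted value (`deriv = 0`) or derivative of
#' order `deriv` with respect to wavenumber at the window center.
#' Derivatives are scaled by the physical grid `spacing` so results are
#' comparable across instruments with different sampling intervals.
#'
#' @param window odd window length (points), > `polyorder`.
#' @param polyorder polynomial degree of the local fit.
#' @param deriv derivative order (0 = smoothing), <= `polyorder`.
#' @param spacing grid spacing (cm-1) used to scale derivatives.
#' @return numeric vector of `window` convolution weights.
#' @examples
#' sg_coefficients(5, 2, 0)  # (-3, 12, 17, 12, -3)/35
#' @export
sg_coefficients <- function(window, polyorder, deriv = 0, spacing = 1) {
  if (window %% 2 != 1 || window <= polyorder) {
    stop("window must be odd and larger than polyorder", call. = FALSE)
  }
  if (deriv > polyorder) stop("deriv must be <= polyorder", call. = FALSE)
  h <- (window - 1) / 2
  x <- (-h:h) * spacing
  X <- outer(x, 0:polyorder, `^`)
  # row (deriv+1) of the pseudo-inverse gives the deriv-th fit coefficient
  pinv <- solve(crossprod(X), t(X))
  factorial(deriv) * pinv[deriv + 1, ]
}

#' Savitzky-Golay smoothing and differentiation
#'
#' Applies the local least-squares polynomial filter to every spectrum.
#' Edge points without a complete centered window — `(window-1)/2` at each
#' end — are dropped from the output grid rather than padded, so no values
#' are invented near the region edges.  The canonical derivative transform
#' for dry-film (HTS) spectra is `window = 15`, `polyorder = 2`,
#' `deriv = 2`, which removes additive and linear baseline structure.
#'
#' @param ds a [spectral_dataset()] on a uniformly spaced grid.
#' @param window odd window length in grid points.
#' @param polyorder local polynomial degree.
#' @param deriv derivative order with respect to wavenumber.
#' @return filtered [spectral_dataset()] on the trimmed grid.
#' @export
savitzky_golay <- function(ds, window = 15, polyorder = 2, deriv = 2) {
  stopifnot(inherits(ds, "spectral_dataset"))
  d <- diff(ds$grid)
  if (length(d) == 0L || max(d) - min(d) > 1e-8 * mean(d)) {
    stop("savitzky_golay requires a uniformly spaced grid; interpolate first",
         call. = FALSE)
  }
  n <- length(ds$grid)
  if (window > n) stop("window exceeds the number of grid points", call. = FALSE)
  w <- sg_coefficients(window, polyorder, deriv, spacing = mean(d))
  h <- (window - 1) / 2
  out_idx <- (h + 1):(n - h)
  # banded operator: column j of S applies the window centered at out_idx[j]
  S <- matrix(0, nrow = n, ncol = length(out_idx))
  for (k in seq_len(window)) {
    S[cbind(out_idx + (k - h - 1L), seq_along(out_idx))] <- w[k]
  }
  spectral_dataset(ds$grid[out_idx], ds$absorbance %*% S, ds$metadata)
}

#' Average technical replicates
#'
#' Collapses the dataset to one spectrum per `sample_id`, the arithmetic
#' mean of its technical replicates; the `technical_replicate` metadata
#' field is cleared and `spectrum_id` becomes the sample id.  Averaging
#' reduces the uncorrelated part of the replicate-to-replicate variation
#' (e.g. film-formation differences in dry-film measurements).
#'
#' @param ds a [spectral_dataset()] whose metadata has `sample_id`.
#' @return the averaged [spectral_dataset()].
#' @export
average_technical_replicates <- function(ds) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (is.null(ds$metadata$sample_id)) {
    stop("metadata must contain sample_id to average replicates", call. = FALSE)
  }
  ids <- ds$metadata$sample_id
  first <- !duplicated(ids)
  order_ids <- ids[first]
  G <- outer(ids, order_ids, `==`) * 1
  G <- G / rep(colSums(G), each = nrow(G))  # column-stochastic averaging
  avg <- t(G) %*% ds$absorbance
  meta <- ds$metadata[first, , drop = FALSE]
  if (!is.null(meta$technical_replicate)) meta$technical_replicate <- NA_integer_
  meta$spectrum_id <- meta$sample_id
  spectral_dataset(ds$grid, avg, meta)
}

#' Standard normal variate (SNV) normalisation
#'
#' Centers each spectrum to mean 0 and scales it to sd 1, removing
#' per-spectrum additive offsets and multiplicative (pathlength) factors.
#'
#' @param ds a [spectral_dataset()] with >= 3 grid points.
#' @return the normalised [spectral_dataset()].
#' @export
snv <- function(ds) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (length(ds$grid) < 3) stop("snv needs at least 3 grid points", call. = FALSE)
  mu <- rowMeans(ds$absorbance)
  sd_ <- apply(ds$absorbance, 1, stats::sd)
  if (any(sd_ < 1e-12)) {
    stop("snv undefined for zero-variance spectra", call. = FALSE)
  }
  spectral_dataset(ds$grid, (ds$absorbance - mu) / sd_, ds$metadata)
}

#' Extended multiplicative signal correction (EMSC)
#'
#' Regresses each spectrum on the reference spectrum plus a quadratic
#' wavenumber baseline, then removes the baseline terms and divides by the
#' multiplicative coefficient:
#' `corrected = (x - a - b*nu - c*nu^2) / m` where
#' `x ~ m*reference + a + b*nu + c*nu^2`.
#'
#' @param ds a [spectral_dataset()].
#' @param reference_spectrum numeric vector on the same grid (e.g. the mean
#'   spectrum).
#' @return the corrected [spectral_dataset()].
#' @export
emsc <- function(ds, reference_spectrum = colMeans(ds$absorbance)) {
  stopifnot(inherits(ds, "spectral_dataset"))
  p <- length(ds$grid)
  if (length(reference_spectrum) != p) {
    stop("reference spectrum must be on the dataset grid", call. = FALSE)
  }
  if (p < 4) stop("emsc needs at least 4 grid points", call. = FALSE)
  u <- 2 * (ds$grid - min(ds$grid)) / (max(ds$grid) - min(ds$grid)) - 1
  M <- cbind(ref = reference_spectrum, const = 1, lin = u, quad = u^2)
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    stop("emsc design matrix is degenerate (reference collinear with baseline terms)",
         call. = FALSE)
  }
  coefs <- t(qr.coef(qrM, t(ds$absorbance)))  # n x 4
  m <- coefs[, "ref"]
  if (any(abs(m) < 1e-12)) {
    stop("emsc multiplicative coefficient is (near) zero for some spectrum",
         call. = FALSE)
  }
  baseline <- coefs[, c("const", "lin", "quad"), drop = FALSE] %*%
    t(M[, c("const", "lin", "quad")])
  spectral_dataset(ds$grid, (ds$absorbance - baseline) / m, ds$metadata)
}

#' Named preprocessing plans
#'
#' A plan freezes the preprocessing chain so it can be applied identically
#' in calibration and prediction.  Two presets mirror the two supernatant
#' measurement tracks:
#'
#' * `"atr_media"` — region 1900-700 cm-1, baseline offset correction only
#'   (liquid ATR spectra are highly reproducible);
#' * `"hts_media"` — region 1900-700 cm-1, Savitzky-Golay second derivative
#'   (window 15 points, polynomial order 2), then technical-replicate
#'   averaging (dry-film spectra vary in effective pathlength; the
#'   derivative removes offset and slope, averaging damps film noise).
#'
#' @param name preset name, or `"custom"` with explicit parameters.
#' @param region_low,region_high region limits (cm-1).
#' @param baseline `"offset"` or `"none"`.
#' @param sg `NULL` or `list(window, polyorder, deriv)`.
#' @param average_replicates average technical replicates at the end?
#' @param normalization `"none"`, `"snv"` or `"emsc"` (applied after the
#'   baseline step, before averaging).
#' @return object of class `preprocess_plan`.
#' @export
preprocess_plan <- function(name = c("custom", "atr_media", "hts_media"),
                            region_low = 1900, region_high = 700,
                            baseline = c("offset", "none"),
                            sg = NULL,
                            average_replicates = FALSE,
                            normalization = c("none", "snv", "emsc")) {
  name <- match.arg(name)
  if (name == "atr_media") {
    baseline <- "offset"; sg <- NULL
    average_replicates <- FALSE; normalization <- "none"
  } else if (name == "hts_media") {
    baseline <- "none"
    sg <- list(window = 15, polyorder = 2, deriv = 2)
    average_replicates <- TRUE; normalization <- "none"
  } else {
    baseline <- match.arg(baseline)
    normalization <- match.arg(normalization)
  }
  if (!is.null(sg)) {
    stopifnot(is.list(sg), all(c("window", "polyorder", "deriv") %in% names(sg)))
    if (sg$window %% 2 != 1 || sg$window <= sg$polyorder || sg$deriv > sg$polyorder) {
      stop("invalid Savitzky-Golay settings: need odd window > polyorder >= deriv",
           call. = FALSE)
    }
  }
  structure(list(name = name,
                 region_low = max(region_low, region_high),
                 region_high = min(region_low, region_high),
                 baseline = baseline, sg = sg,
                 average_replicates = average_replicates,
                 normalization = normalization),
            class = "preprocess_plan")
}

#' @export
print.preprocess_plan <- function(x, ...) {
  steps <- c(sprintf("region %g-%g cm-1", x$region_low, x$region_high),
             if (x$baseline == "offset") "baseline offset",
             if (!is.null(x$sg)) sprintf("SG %d/%d deriv %d", x$sg$window,
                                         x$sg$polyorder, x$sg$deriv),
             if (x$normalization != "none") x$normalization,
             if (x$average_replicates) "replicate averaging")
  cat(sprintf("<preprocess_plan '%s'> %s\n", x$name,
              paste(steps, collapse = " -> ")))
  invisible(x)
}

#' Apply a preprocessing plan
#'
#' Executes the plan's steps in their fixed order: region selection,
#' baseline, Savitzky-Golay, normalization, replicate averaging.  Applying
#' the same plan to the same input is bit-identical (no randomness, no
#' data-dependent state beyond the per-spectrum operations themselves).
#'
#' @param ds a [spectral_dataset()].
#' @param plan a [preprocess_plan()] or preset name.
#' @param emsc_reference reference spectrum for `normalization = "emsc"`
#'   (default: region-restricted mean spectrum).
#' @return the preprocessed [spectral_dataset()].
#' @export
apply_plan <- function(ds, plan = "hts_media", emsc_reference = NULL) {
  if (is.character(plan)) plan <- preprocess_plan(plan)
  stopifnot(inherits(plan, "preprocess_plan"))
  out <- select_region(ds, plan$region_low, plan$region_high)
  if (plan$baseline == "offset") out <- baseline_offset(out)
  if (!is.null(plan$sg)) {
    out <- savitzky_golay(out, plan$sg$window, plan$sg$polyorder, plan$sg$deriv)
  }
  if (plan$normalization == "snv") out <- snv(out)
  if (plan$normalization == "emsc") {
    ref <- if (is.null(emsc_reference)) colMeans(out$absorbance) else emsc_reference
    out <- emsc(out, ref)
  }
  if (plan$average_replicates) out <- average_technical_replicates(out)
  out
}
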