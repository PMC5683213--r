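#' Spectral dataset container
#'
#' Bundles a shared wavenumber grid, an absorbance matrix (one row per
#' spectrum) and a per-spectrum metadata table.  The grid is stored strictly
#' increasing; a descending grid (the usual FTIR presentation convention) is
#' accepted and silently reversed together with the matrix columns.
#'
#' @param grid numeric vector of wavenumbers (cm-1), strictly monotone.
#' @param absorbance numeric matrix, spectra in rows, `length(grid)` columns
#'   of absorbance values (AU).
#' @param metadata data frame with one row per spectrum.  A `spectrum_id`
#'   column is added if absent.
#' @return An object of class `spectral_dataset`: a list with elements
#'   `grid`, `absorbance` and `metadata`.
#' @examples
#' ds <- spectral_dataset(seq(700, 1900, 2),
#'                        matrix(rnorm(2 * 601), nrow = 2),
#'                        data.frame(sample_id = c("a", "b")))
#' ds
#' @export
spectral_dataset <- function(grid, absorbance, metadata) {
  grid <- as.numeric(grid)
  if (length(grid) < 1L) {
    stop("grid must contain at least one wavenumber", call. = FALSE)
  }
  if (is.null(dim(absorbance))) {
    absorbance <- matrix(absorbance, nrow = 1L)
  }
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  d <- diff(grid)
  if (length(d) > 0L) {
    if (all(d < 0)) {
      grid <- rev(grid)
      absorbance <- absorbance[, rev(seq_along(grid)), drop = FALSE]
    } else if (any(d <= 0)) {
      stop("grid must be strictly monotone (duplicated or unordered wavenumbers)",
           call. = FALSE)
    }
  }
  if (ncol(absorbance) != length(grid)) {
    stop("absorbance must have one column per grid point (",
         ncol(absorbance), " columns vs ", length(grid), " grid points)",
         call. = FALSE)
  }
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (nrow(metadata) != nrow(absorbance)) {
    stop("metadata must have one row per spectrum", call. = FALSE)
  }
  if (anyNA(absorbance)) {
    stop("absorbance matrix must not contain missing values", call. = FALSE)
  }
  if (is.null(metadata$spectrum_id)) {
    metadata$spectrum_id <- if (!is.null(rownames(absorbance))) {
      rownames(absorbance)
    } else {
      sprintf("spectrum_%04d", seq_len(nrow(metadata)))
    }
  }
  rownames(absorbance) <- metadata$spectrum_id
  structure(list(grid = grid, absorbance = absorbance, metadata = metadata),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d spectra x %d wavenumbers (%g-%g cm-1)\n",
              nrow(x$absorbance), length(x$grid),
              min(x$grid), max(x$grid)))
  types <- table(x$metadata$sample_type)
  if (length(types)) {
    cat("  sample types:",
        paste(sprintf("%s (%d)", names(types), types), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of spectra in a dataset
#' @param ds a [spectral_dataset()].
#' @return integer count of spectra (matrix rows).
#' @export
n_spectra <- function(ds) {
  stopifnot(inherits(ds, "spectral_dataset"))
  nrow(ds$absorbance)
}

#' Subset spectra
#'
#' `ds[i]` keeps the spectra selected by `i` (logical, integer or
#' spectrum-id character index); the grid is unchanged.
#'
#' @param x a [spectral_dataset()].
#' @param i spectrum index.
#' @param ... ignored.
#' @export
`[.spectral_dataset` <- function(x, i, ...) {
  if (is.character(i)) {
    i <- match(i, x$metadata$spectrum_id)
    if (anyNA(i)) stop("unknown spectrum_id in subset", call. = FALSE)
  }
  spectral_dataset(x$grid,
                   x$absorbance[i, , drop = FALSE],
                   x$metadata[i, , drop = FALSE])
}

#' Index of the grid point nearest a wavenumber
#' @param ds a [spectral_dataset()].
#' @param wavenumber target position (cm-1).
#' @return integer column index into `ds$absorbance`.
#' @export
wavenumber_index <- function(ds, wavenumber) {
  which.min(abs(ds$grid - wavenumber))
}
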