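#' Write a spectral dataset as a wide CSV
#'
#' First column `wavenumber`, then one absorbance column per spectrum named
#' by its `spectrum_id`.  Values are written with 15 significant digits so
#' a write/read round trip reproduces them to better than 1e-12 relative.
#' Metadata travels in a separate table (see [utils::write.csv()]); the
#' reader re-attaches it by `spectrum_id`.
#'
#' @param ds a [spectral_dataset()].
#' @param path output file.
#' @param descending write the grid in descending wavenumber order (the
#'   FTIR presentation convention)?  Internally the grid stays ascending.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(ds, path, descending = FALSE) {
  stopifnot(inherits(ds, "spectral_dataset"))
  ord <- if (descending) rev(seq_along(ds$grid)) else seq_along(ds$grid)
  tab <- data.frame(wavenumber = ds$grid[ord],
                    t(ds$absorbance[, ord, drop = FALSE]),
                    check.names = FALSE)
  names(tab) <- c("wavenumber", ds$metadata$spectrum_id)
  num <- vapply(tab, function(col) format(col, digits = 15, trim = TRUE,
                                          scientific = NA),
                character(nrow(tab)))
  utils::write.table(num, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a wide-CSV spectral dataset
#'
#' Expects the layout written by [write_spectra_csv()]: a `wavenumber`
#' first column and one numeric column per spectrum.  Descending grids are
#' normalised to ascending (recorded in the `descending_input` attribute);
#' duplicated or non-monotone wavenumbers, ragged rows and non-numeric
#' cells are rejected with the offending line number.
#'
#' @param path input CSV.
#' @param metadata optional per-spectrum metadata data frame carrying a
#'   `spectrum_id` column matching the CSV column names.
#' @return a [spectral_dataset()].
#' @export
read_spectra_csv <- function(path, metadata = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("spectra CSV has no data rows", call. = FALSE)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  ncol_exp <- length(header)
  cells <- strsplit(lines[-1], ",", fixed = TRUE)
  bad <- which(lengths(cells) != ncol_exp)
  if (length(bad)) {
    stop("ragged row at line ", bad[1] + 1L, ": expected ", ncol_exp,
         " cells, found ", lengths(cells)[bad[1]], call. = FALSE)
  }
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(cells)), ncol = ncol_exp, byrow = TRUE))
  if (anyNA(vals)) {
    bad_line <- which(apply(vals, 1, anyNA))[1]
    stop("non-numeric cell at line ", bad_line + 1L, call. = FALSE)
  }
  grid <- vals[, 1]
  if (anyDuplicated(grid)) {
    stop("duplicated wavenumber at line ",
         which(duplicated(grid))[1] + 1L, call. = FALSE)
  }
  d <- diff(grid)
  descending <- length(d) > 0 && all(d < 0)
  if (length(d) > 0 && !descending && any(d <= 0)) {
    stop("wavenumber column is not monotone (first violation at line ",
         which(d <= 0)[1] + 2L, ")", call. = FALSE)
  }
  abs_mat <- t(vals[, -1, drop = FALSE])
  ids <- header[-1]
  if (is.null(metadata)) {
    metadata <- data.frame(spectrum_id = ids, stringsAsFactors = FALSE)
  } else {
    m <- match(ids, metadata$spectrum_id)
    if (anyNA(m)) {
      stop("metadata lacks spectrum_id(s): ",
           paste(ids[is.na(m)][1:5], collapse = ", "), call. = FALSE)
    }
    metadata <- metadata[m, , drop = FALSE]
  }
  ds <- spectral_dataset(grid, abs_mat, metadata)
  attr(ds, "descending_input") <- descending
  ds
}

#' Read a single spectrum from a JCAMP-DX file
#'
#' Supports uncompressed AFFN/PAC numeric tables in `##XYDATA=(X++(Y..Y))`
#' form (x value followed by y values per line, with `##FIRSTX`, `##LASTX`,
#' `##NPOINTS`, and optional `##XFACTOR`/`##YFACTOR` scaling) and
#' `##XYPOINTS=(XY..XY)` pair lists.  Compressed SQZ/DIF/DUP encodings are
#' rejected with an explicit message.
#'
#' @param path JCAMP-DX file.
#' @return list with `grid` (ascending) and `absorbance` vectors plus
#'   `title`.
#' @export
read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lbl <- function(name) {
    hit <- grep(paste0("^##", name, "="), lines, ignore.case = TRUE)
    if (length(hit)) sub("^##[^=]+=", "", lines[hit[1]]) else NULL
  }
  for (req in c("TITLE", "END")) {
    if (!any(grepl(paste0("^##", req), lines, ignore.case = TRUE))) {
      stop("JCAMP-DX file lacks required label ##", req, call. = FALSE)
    }
  }
  xy_start <- grep("^##(XYDATA|XYPOINTS)=", lines, ignore.case = TRUE)
  if (!length(xy_start)) {
    stop("JCAMP-DX file lacks required label ##XYDATA or ##XYPOINTS",
         call. = FALSE)
  }
  xy_start <- xy_start[1]
  form <- toupper(sub("^##([A-Za-z]+)=.*", "\\1", lines[xy_start]))
  end <- grep("^##", lines)
  end <- end[end > xy_start][1]
  if (is.na(end)) stop("unterminated data block (missing ##END)", call. = FALSE)
  body <- lines[(xy_start + 1):(end - 1)]
  body <- body[nzchar(trimws(body))]
  if (any(grepl("[A-Za-z@%]", gsub("[Ee][+-]?[0-9]+", "", body)))) {
    stop("compressed JCAMP encodings (SQZ/DIF/DUP) are not supported; ",
         "export the file in AFFN (uncompressed) form", call. = FALSE)
  }
  xf <- as.numeric(lbl("XFACTOR") %||% "1")
  yf <- as.numeric(lbl("YFACTOR") %||% "1")
  if (form == "XYPOINTS") {
    nums <- as.numeric(unlist(strsplit(gsub(";", ",", paste(body, collapse = ",")),
                                       "[,[:space:]]+")))
    nums <- nums[!is.na(nums)]
    if (length(nums) %% 2 != 0) stop("odd number of XY values", call. = FALSE)
    x <- nums[seq(1, length(nums), 2)] * xf
    y <- nums[seq(2, length(nums), 2)] * yf
  } else {
    x <- numeric(0); y <- numeric(0)
    npt <- as.numeric(lbl("NPOINTS") %||% NA)
    for (ln in body) {
      nums <- as.numeric(strsplit(trimws(ln), "[,[:space:]]+")[[1]])
      if (anyNA(nums) || length(nums) < 2) {
        stop("unparseable XYDATA line: ", ln, call. = FALSE)
      }
      x0 <- nums[1] * xf
      ys <- nums[-1] * yf
      # x of subsequent points interpolated from FIRSTX/LASTX/NPOINTS
      dx <- if (!is.na(npt) && npt > 1) {
        (as.numeric(lbl("LASTX")) - as.numeric(lbl("FIRSTX"))) / (npt - 1)
      } else {
        NA_real_
      }
      if (is.na(dx)) stop("##NPOINTS/##FIRSTX/##LASTX needed for XYDATA",
                          call. = FALSE)
      x <- c(x, x0 + dx * (seq_along(ys) - 1))
      y <- c(y, ys)
    }
  }
  if (any(diff(x) < 0)) { o <- order(x); x <- x[o]; y <- y[o] }
  list(grid = x, absorbance = y,
       title = lbl("TITLE") %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
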