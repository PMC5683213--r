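#' Cross-validation segments by experimental condition
#'
#' Assigns every spectrum to a segment so that all technical and biological
#' replicates of one experimental condition are held out together:
#' supernatant spectra are grouped per (strain, temperature, day) and
#' starting-growth-medium spectra per temperature.  For the full screening
#' design this yields 74 segments (72 condition segments + 2 media
#' segments), each holding 9 spectra before replicate averaging or 3 after.
#'
#' @param metadata per-spectrum metadata with columns `strain`,
#'   `temperature`, `day`, `sample_type`.
#' @return character vector of segment labels, one per row, sorted order
#'   deterministic in (strain, temperature, day).
#' @export
build_segments <- function(metadata) {
  need <- c("strain", "temperature", "day", "sample_type")
  missing_k <- setdiff(need, names(metadata))
  if (length(missing_k)) {
    stop("metadata lacks grouping key(s): ",
         paste(missing_k, collapse = ", "), call. = FALSE)
  }
  ifelse(metadata$sample_type == "medium",
         sprintf("medium_%gC", metadata$temperature),
         sprintf("%s_%gC_d%02d", metadata$strain, metadata$temperature,
                 metadata$day))
}

#' Segmented cross-validation of a PLS1 calibration
#'
#' For each segment in turn, fits PLS1 models with 1..`a_max` components on
#' all other segments (centering recomputed on each training fold) and
#' predicts the held-out spectra; `rmsecv(A)` pools the held-out squared
#' errors over all segments.  Because folds are whole segments, replicates
#' of one condition never straddle the train/test boundary — this is
#' asserted on every run.
#'
#' @param X spectra matrix or [spectral_dataset()].
#' @param y reference concentrations (g/L), one per spectrum.
#' @param segments segment label per spectrum (see [build_segments()]).
#' @param a_max largest number of components to evaluate.
#' @param tolerance relative tolerance of the component-selection rule.
#' @param a_opt_method `"relative"` or `"one_se"` (see [select_a_opt()]).
#' @return object of class `cv_result`: list with `rmsecv` (by A),
#'   `rmsecv_se` (segment-level SE by A), `a_opt`, `predictions`
#'   (n x a_max matrix of held-out predictions), `segments`, `n_segments`.
#' @export
segmented_cross_validation <- function(X, y, segments, a_max = 10,
                                       tolerance = 0.02,
                                       a_opt_method = "relative") {
  if (inherits(X, "spectral_dataset")) X <- X$absorbance
  X <- as.matrix(X)
  y <- as.numeric(y)
  segments <- as.character(segments)
  stopifnot(nrow(X) == length(y), length(segments) == length(y))
  folds <- sort(unique(segments))
  if (length(folds) < 2) {
    stop("cross-validation needs at least 2 segments", call. = FALSE)
  }
  a_max <- min(a_max, nrow(X) - max(table(segments)) - 1L, ncol(X))
  if (a_max < 1) stop("a segment contains (almost) all samples", call. = FALSE)
  n <- nrow(X)
  preds <- matrix(NA_real_, n, a_max)
  for (seg in folds) {
    test <- segments == seg
    # leakage guard: the held-out condition must be absent from training
    if (any(segments[!test] == seg)) {
      stop("leakage: segment '", seg, "' present in its own training fold",
           call. = FALSE)
    }
    fit <- fit_plsr(X[!test, , drop = FALSE], y[!test], a_max, strict = FALSE)
    for (a in seq_len(a_max)) {
      preds[test, a] <- predict(fit, X[test, , drop = FALSE],
                                ncomp = min(a, fit$ncomp))
    }
  }
  err2 <- (preds - y)^2
  rmsecv <- sqrt(colMeans(err2))
  seg_rmse <- rowsum(err2, segments)          # per-segment SSE by A
  seg_n <- as.vector(table(segments)[rownames(seg_rmse)])
  seg_rmse <- sqrt(seg_rmse / seg_n)
  se <- apply(seg_rmse, 2, stats::sd) / sqrt(length(folds))
  a_opt <- select_a_opt(rmsecv, tolerance, method = a_opt_method, se = se)
  structure(list(rmsecv = rmsecv, rmsecv_se = se, a_opt = a_opt,
                 predictions = preds, segments = segments,
                 n_segments = length(folds)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d segments, A_opt = %d, RMSECV(A_opt) = %.4g\n",
              x$n_segments, x$a_opt, x$rmsecv[x$a_opt]))
  invisible(x)
}

#' Independent-test split by strain and temperature
#'
#' Holds out every supernatant spectrum of one strain x temperature
#' condition as an independent test set; everything else trains the model.
#' Growth-medium spectra (which carry no strain) are never placed in the
#' test set; their inclusion in training is a policy flag.
#'
#' @param metadata per-spectrum metadata.
#' @param strain held-out strain label (`NULL` for no hold-out: everything
#'   trains).
#' @param temperature held-out temperature (degrees C).
#' @param include_media keep medium spectra in the training set?
#' @return list with integer vectors `train` and `test` (row indices).
#' @export
independent_test_split <- function(metadata, strain, temperature,
                                   include_media = TRUE) {
  n <- nrow(metadata)
  if (is.null(strain)) {
    test <- rep(FALSE, n)
  } else {
    test <- !is.na(metadata$strain) & metadata$strain == strain &
      metadata$temperature == temperature &
      metadata$sample_type != "medium"
    if (!any(test)) {
      stop("hold-out condition ", strain, " at ", temperature,
           " C not present in the metadata", call. = FALSE)
    }
  }
  train <- !test
  if (!include_media) train <- train & metadata$sample_type != "medium"
  list(train = which(train), test = which(test))
}

#' Run the full calibration workflow for one analyte and mode
#'
#' Orchestrates the complete analysis: applies the mode's frozen
#' preprocessing plan (`atr_media` or `hts_media`), restricts the spectra
#' per the analyte rule (glucose models use all strains; citric-acid
#' models only the producer strains, identified from the reference table,
#' plus growth media), aligns reference concentrations by `sample_id`, and
#' validates by segmented cross-validation and/or independent-test
#' validation.
#'
#' Media-inclusion defaults follow the two analytes' training-set
#' arithmetic: glucose models exclude media from the independent-test
#' training set while citric-acid models include them; segmented CV always
#' includes media (as their own per-temperature segments).  For ITV the
#' number of components is chosen by segmented CV within the training set
#' only, then a single model is fitted on all training spectra and applied
#' to the held-out condition.
#'
#' @param dataset raw [spectral_dataset()] (unpreprocessed).
#' @param reference data frame `sample_id`, `glucose`, `citric_acid` (g/L).
#' @param analyte `"glucose"` or `"citric_acid"`.
#' @param mode `"ATR"` or `"HTS"` — selects the frozen preprocessing plan.
#' @param scheme any of `"CV"`, `"ITV"`.
#' @param holdout `list(strain=, temperature=)` for ITV; default: the
#'   (first) producer strain at 30 C.
#' @param a_max largest number of components scanned.
#' @param tolerance component-selection tolerance (see [select_a_opt()]).
#' @param reference_scale denominator of relative RMSE (default: maximum
#'   reference concentration in the calibration data).
#' @param include_media_itv_train override of the media policy for the ITV
#'   training set (`NULL` = analyte default).
#' @return object of class `calibration_report`.
#' @export
run_calibration_workflow <- function(dataset, reference,
                                     analyte = c("glucose", "citric_acid"),
                                     mode = c("HTS", "ATR"),
                                     scheme = c("CV", "ITV"),
                                     holdout = NULL,
                                     a_max = 10, tolerance = 0.02,
                                     reference_scale = NULL,
                                     include_media_itv_train = NULL) {
  analyte <- match.arg(analyte)
  mode <- match.arg(mode)
  scheme <- match.arg(scheme, several.ok = TRUE)
  if (!analyte %in% names(reference)) {
    stop("analyte '", analyte, "' absent from the reference table",
         call. = FALSE)
  }
  plan <- preprocess_plan(if (mode == "ATR") "atr_media" else "hts_media")
  ds <- apply_plan(dataset, plan)
  meta <- ds$metadata

  producers <- stats::na.omit(unique(
    meta$strain[match(reference$sample_id[reference$citric_acid > 0],
                      meta$sample_id)]))
  if (analyte == "citric_acid") {
    if (length(producers) == 0) {
      stop("no citric-acid producer strain found in the reference table",
           call. = FALSE)
    }
    keep <- meta$sample_type == "medium" |
      (!is.na(meta$strain) & meta$strain %in% producers)
    ds <- ds[which(keep)]
    meta <- ds$metadata
  }

  idx <- match(meta$sample_id, reference$sample_id)
  if (anyNA(idx)) {
    stop("reference table lacks sample(s): ",
         paste(unique(meta$sample_id[is.na(idx)])[1:5], collapse = ", "),
         call. = FALSE)
  }
  y <- reference[[analyte]][idx]
  if (is.null(reference_scale)) reference_scale <- max(y)
  segments <- build_segments(meta)
  assert_no_leakage(meta, segments)

  report <- list(analyte = analyte, mode = mode, plan = plan,
                 n_spectra = n_spectra(ds),
                 reference_scale = reference_scale, schemes = list())

  if ("CV" %in% scheme) {
    cv <- segmented_cross_validation(ds, y, segments, a_max, tolerance)
    pred <- cv$predictions[, cv$a_opt]
    report$schemes$CV <- list(
      a_opt = cv$a_opt,
      metrics = compute_metrics(y, pred, reference_scale),
      rmsecv = cv$rmsecv, rmsecv_se = cv$rmsecv_se,
      n_segments = cv$n_segments,
      predictions = data.frame(sample_id = meta$sample_id,
                               spectrum_id = meta$spectrum_id,
                               segment = segments,
                               y_true = y, y_pred = pred,
                               stringsAsFactors = FALSE))
  }

  if ("ITV" %in% scheme) {
    if (is.null(holdout)) {
      if (length(producers) == 0) {
        stop("no producer strain available for the default hold-out; supply one",
             call. = FALSE)
      }
      holdout <- list(strain = producers[1], temperature = 30)
    }
    include_media <- if (!is.null(include_media_itv_train)) {
      include_media_itv_train
    } else {
      analyte == "citric_acid"
    }
    split <- independent_test_split(ds$metadata, holdout$strain,
                                    holdout$temperature, include_media)
    if (length(split$test) == 0) {
      stop("ITV requested but the hold-out selects no spectra", call. = FALSE)
    }
    tr <- split$train; te <- split$test
    inner <- segmented_cross_validation(ds$absorbance[tr, , drop = FALSE],
                                        y[tr], segments[tr], a_max, tolerance)
    fit <- fit_plsr(ds$absorbance[tr, , drop = FALSE], y[tr], inner$a_opt)
    pred <- predict(fit, ds$absorbance[te, , drop = FALSE])
    report$schemes$ITV <- list(
      a_opt = inner$a_opt,
      holdout = holdout,
      metrics = compute_metrics(y[te], pred, reference_scale),
      n_train = length(tr), n_test = length(te),
      model = fit,
      predictions = data.frame(sample_id = ds$metadata$sample_id[te],
                               spectrum_id = ds$metadata$spectrum_id[te],
                               y_true = y[te], y_pred = pred,
                               stringsAsFactors = FALSE))
  }
  structure(report, class = "calibration_report")
}

# every CV fold must keep whole conditions: identical (strain, temperature,
# day, sample_type-group) keys must map to a single segment and vice versa
assert_no_leakage <- function(metadata, segments) {
  key <- ifelse(metadata$sample_type == "medium",
                paste("medium", metadata$temperature),
                paste(metadata$strain, metadata$temperature, metadata$day))
  if (any(tapply(segments, key, function(s) length(unique(s))) != 1)) {
    stop("internal error: an experimental condition straddles CV segments",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("Calibration report: %s, %s mode (%d spectra, scale %.3g g/L)\n",
              x$analyte, x$mode, x$n_spectra, x$reference_scale))
  cat(sprintf("  %-4s %-10s %-14s %s\n", "", "R2 (A_opt)", "RMSE (rel)", "n"))
  for (nm in names(x$schemes)) {
    s <- x$schemes[[nm]]
    cat(sprintf("  %-4s %.2f (%d)   %.2f (%.1f%%)    %d\n",
                nm, s$metrics$r2, s$a_opt, s$metrics$rmse,
                s$metrics$rmse_pct, s$metrics$n))
  }
  invisible(x)
}
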