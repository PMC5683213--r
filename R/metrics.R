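#' Calibration validation metrics
#'
#' Root-mean-square error, relative RMSE and coefficient of determination:
#' `rmse = sqrt(mean((y_hat - y)^2))`,
#' `r2 = 1 - SSE/SST` (SST about the mean of `y_true` — the coefficient of
#' determination, not a squared correlation), and
#' `rmse_pct = 100 * rmse / reference_scale`.  The reference scale defaults
#' to the maximum reference concentration, the convention under which an
#' error of 3.59 g/L on an 80 g/L glucose range reads 4.5%.
#'
#' @param y_true reference concentrations (g/L).
#' @param y_pred predicted concentrations (g/L).
#' @param reference_scale denominator (g/L) of the relative error.
#' @return list with `rmse`, `rmse_pct`, `r2`, `n`, `reference_scale`.
#' @examples
#' compute_metrics(c(0, 2), c(1, 1))  # rmse 1, r2 0
#' @export
compute_metrics <- function(y_true, y_pred,
                            reference_scale = max(abs(y_true))) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred) || length(y_true) < 2) {
    stop("y_true and y_pred must have equal length >= 2", call. = FALSE)
  }
  sst <- sum((y_true - mean(y_true))^2)
  if (sst < 1e-24) {
    stop("r2 undefined: y_true has zero variance", call. = FALSE)
  }
  sse <- sum((y_pred - y_true)^2)
  rmse <- sqrt(mean((y_pred - y_true)^2))
  list(rmse = rmse,
       rmse_pct = 100 * rmse / reference_scale,
       r2 = 1 - sse / sst,
       n = length(y_true),
       reference_scale = reference_scale)
}

#' Parsimonious choice of the number of PLS components
#'
#' Returns the smallest number of components whose cross-validated RMSE is
#' only insignificantly above the curve minimum.  "Insignificant" is
#' operationalised as a relative tolerance: the smallest `A` with
#' `rmsecv(A) <= (1 + tolerance) * min(rmsecv)`.  An alternative
#' one-standard-error rule accepts the smallest `A` with
#' `rmsecv(A) <= rmsecv(A*) + se[A*]`, using segment-level standard errors.
#'
#' @param rmsecv numeric vector of cross-validated RMSE values, indexed by
#'   the number of components 1..length(rmsecv); values >= 0.
#' @param tolerance relative slack above the minimum (default 0.02).
#' @param method `"relative"` (default) or `"one_se"`.
#' @param se segment-level standard errors of `rmsecv` (required for
#'   `"one_se"`).
#' @return integer `A_opt`.
#' @examples
#' select_a_opt(c(5.0, 3.60, 3.59, 3.58))  # 2
#' @export
select_a_opt <- function(rmsecv, tolerance = 0.02,
                         method = c("relative", "one_se"), se = NULL) {
  method <- match.arg(method)
  rmsecv <- as.numeric(rmsecv)
  if (length(rmsecv) == 0 || any(rmsecv < 0) || anyNA(rmsecv)) {
    stop("rmsecv must be a non-empty vector of non-negative values",
         call. = FALSE)
  }
  i_min <- which.min(rmsecv)
  threshold <- if (method == "relative") {
    (1 + tolerance) * rmsecv[i_min]
  } else {
    if (is.null(se) || length(se) != length(rmsecv)) {
      stop("one_se rule needs per-A standard errors", call. = FALSE)
    }
    rmsecv[i_min] + se[i_min]
  }
  which(rmsecv <= threshold)[1]
}
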