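#' Principal component analysis of a spectral matrix
#'
#' Column-mean-centered PCA via singular value decomposition.  Loadings are
#' unit-norm and mutually orthogonal; explained variance percentages are
#' relative to the total variance (so over all possible components they sum
#' to 100).  Component signs are fixed deterministically: the
#' largest-magnitude element of each loading is made positive, so repeated
#' runs are bit-identical.
#'
#' @param X spectra matrix (rows = spectra) or a [spectral_dataset()].
#' @param n_components number of components to retain (default: all).
#' @return object of class `pca_model`: list with `mean_spectrum`,
#'   `loadings` (components x variables), `scores`
#'   (spectra x components), `explained_variance_pct` (retained
#'   components) and `all_variance_pct` (every possible component).
#' @examples
#' X <- matrix(rnorm(40), nrow = 8)
#' fit_pca(X, 2)$explained_variance_pct
#' @export
fit_pca <- function(X, n_components = NULL) {
  if (inherits(X, "spectral_dataset")) X <- X$absorbance
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("PCA needs at least 2 spectra", call. = FALSE)
  mu <- colMeans(X)
  Xc <- X - rep(mu, each = n)
  total <- sum(Xc^2)
  if (total < 1e-24) stop("constant matrix: no variance to decompose", call. = FALSE)
  k_max <- min(n - 1L, ncol(X))
  if (is.null(n_components)) n_components <- k_max
  if (n_components > k_max) {
    stop("n_components must be <= min(rows - 1, cols)", call. = FALSE)
  }
  sv <- svd(Xc)
  all_pct <- 100 * sv$d^2 / total
  keep <- seq_len(n_components)
  loadings <- t(sv$v[, keep, drop = FALSE])
  scores <- sv$u[, keep, drop = FALSE] *
    rep(sv$d[keep], each = n)
  # deterministic sign: largest |loading| element positive per component
  for (a in keep) {
    j <- which.max(abs(loadings[a, ]))
    if (loadings[a, j] < 0) {
      loadings[a, ] <- -loadings[a, ]
      scores[, a] <- -scores[, a]
    }
  }
  structure(list(mean_spectrum = mu,
                 loadings = loadings,
                 scores = scores,
                 explained_variance_pct = all_pct[keep],
                 all_variance_pct = all_pct[seq_len(k_max)]),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  k <- min(5L, length(x$explained_variance_pct))
  cat(sprintf("<pca_model> %d components; variance%%: %s\n",
              nrow(x$loadings),
              paste(sprintf("%.2f", x$explained_variance_pct[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}

#' Project new spectra onto a fitted PCA model
#' @param object a `pca_model`.
#' @param newdata matrix or [spectral_dataset()] on the training grid.
#' @param ... ignored.
#' @return score matrix (spectra x components).
#' @export
predict.pca_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectral_dataset")) newdata <- newdata$absorbance
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$mean_spectrum)) {
    stop("newdata grid does not match the training grid", call. = FALSE)
  }
  (newdata - rep(object$mean_spectrum, each = nrow(newdata))) %*%
    t(object$loadings)
}
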