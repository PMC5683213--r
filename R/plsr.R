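#' PLS1 regression by NIPALS
#'
#' Single-response partial least squares regression with mean centering of
#' `X` and `y` and per-component deflation of `X` (the classical NIPALS
#' algorithm, which for one response requires no inner iteration).  The
#' model exposes both the component form (weights, loadings, scores) and
#' the collapsed regression vector `b` with
#' `b = W (P'W)^{-1} q`, so that predictions are
#' `y_mean + (X - x_mean) b`.
#'
#' @param X predictor matrix (spectra in rows) or a [spectral_dataset()].
#' @param y numeric response (concentrations, g/L), one per row of `X`.
#' @param ncomp number of latent components A (>= 1).
#' @param strict if `TRUE` (default) an `ncomp` exceeding the effective
#'   rank of centered `X` is an error; if `FALSE` extraction stops early
#'   and the fitted model carries fewer components.
#' @return object of class `pls1_model`: list with `ncomp`, `x_mean`,
#'   `y_mean`, `weights` (p x A), `x_loadings` (p x A), `y_loadings`
#'   (length A), `scores` (n x A), `coefficients` (regression vector,
#'   length p) and optionally `grid`.
#' @examples
#' X <- matrix(rnorm(200), nrow = 20)
#' y <- X[, 3] * 2 + 5
#' m <- fit_plsr(X, y, 1)
#' max(abs(predict(m, X) - y)) < 1e-8
#' @export
fit_plsr <- function(X, y, ncomp, strict = TRUE) {
  grid <- NULL
  if (inherits(X, "spectral_dataset")) {
    grid <- X$grid
    X <- X$absorbance
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (n < 2 || stats::var(y) < 1e-24) {
    stop("y must vary: zero-variance response cannot be calibrated", call. = FALSE)
  }
  if (ncomp < 1) stop("ncomp must be >= 1", call. = FALSE)
  if (ncomp > min(n - 1L, p)) {
    stop("ncomp exceeds min(rows - 1, cols)", call. = FALSE)
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- X - rep(x_mean, each = n)
  f <- y - y_mean
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  tt1 <- NULL
  a_done <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, f)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-14) { if (strict) stop_rank(a) else break }
    w <- w / wn
    t_ <- E %*% w
    tt <- sum(t_^2)
    if (is.null(tt1)) tt1 <- tt
    if (tt < tt1 * 1e-24) { if (strict) stop_rank(a) else break }
    p_ <- crossprod(E, t_) / tt
    q_ <- sum(f * t_) / tt
    E <- E - t_ %*% t(p_)
    f <- f - q_ * t_
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_; q[a] <- q_
    a_done <- a
  }
  if (a_done == 0L) stop_rank(1L)
  W <- W[, seq_len(a_done), drop = FALSE]
  P <- P[, seq_len(a_done), drop = FALSE]
  Tm <- Tm[, seq_len(a_done), drop = FALSE]
  q <- q[seq_len(a_done)]
  structure(list(ncomp = a_done,
                 x_mean = x_mean, y_mean = y_mean,
                 weights = W, x_loadings = P, y_loadings = q,
                 scores = Tm,
                 coefficients = pls_coefficients(W, P, q, a_done),
                 grid = grid),
            class = "pls1_model")
}

stop_rank <- function(a) {
  stop("requested number of components exceeds the rank of the centered ",
       "predictor matrix (failed at component ", a, ")", call. = FALSE)
}

# regression vector using the first `a` components
pls_coefficients <- function(W, P, q, a) {
  Wa <- W[, seq_len(a), drop = FALSE]
  drop(Wa %*% solve(crossprod(P[, seq_len(a), drop = FALSE], Wa),
                    q[seq_len(a)]))
}

#' @export
print.pls1_model <- function(x, ...) {
  cat(sprintf("<pls1_model> A = %d components, %d variables, y_mean = %.4g\n",
              x$ncomp, length(x$x_mean), x$y_mean))
  invisible(x)
}

#' Predict concentrations from a PLS1 model
#'
#' `y_hat = y_mean + (X - x_mean) b`, with `b` the regression vector of the
#' first `ncomp` components.
#'
#' @param object a `pls1_model`.
#' @param newdata matrix or [spectral_dataset()]; if the model was fitted
#'   on a dataset, the grid must match.
#' @param ncomp number of components to use (default: all fitted).
#' @param ... ignored.
#' @return numeric vector of predictions.
#' @export
predict.pls1_model <- function(object, newdata, ncomp = object$ncomp, ...) {
  if (inherits(newdata, "spectral_dataset")) {
    if (!is.null(object$grid) &&
        (length(newdata$grid) != length(object$grid) ||
         max(abs(newdata$grid - object$grid)) > 1e-8)) {
      stop("newdata wavenumber grid does not match the training grid",
           call. = FALSE)
    }
    newdata <- newdata$absorbance
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean)) {
    stop("newdata has ", ncol(newdata), " variables; model expects ",
         length(object$x_mean), call. = FALSE)
  }
  if (ncomp < 1 || ncomp > object$ncomp) {
    stop("ncomp must be between 1 and the fitted number of components",
         call. = FALSE)
  }
  b <- if (ncomp == object$ncomp) {
    object$coefficients
  } else {
    pls_coefficients(object$weights, object$x_loadings, object$y_loadings,
                     ncomp)
  }
  drop(object$y_mean +
         (newdata - rep(object$x_mean, each = nrow(newdata))) %*% b)
}
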