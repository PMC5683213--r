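# Independent oracles used to cross-check the package's own implementations.
# These deliberately take different algorithmic routes than the code under
# test (SIMPLS vs NIPALS, normal equations vs latent variables).

# PLS1 by the SIMPLS algorithm (de Jong 1993): no deflation of X, basis
# vectors orthogonalised in loading space.  For a single response SIMPLS and
# NIPALS PLS1 give identical regression vectors.
simpls_pls1 <- function(X, y, a_max) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xc <- X - rep(x_mean, each = n)
  yc <- y - y_mean
  s <- crossprod(Xc, yc)
  R <- matrix(0, p, a_max); V <- matrix(0, p, a_max); q <- numeric(a_max)
  for (a in seq_len(a_max)) {
    r <- s
    t_ <- Xc %*% r
    nt <- sqrt(sum(t_^2))
    t_ <- t_ / nt; r <- r / nt
    pp <- crossprod(Xc, t_)
    q[a] <- sum(yc * t_)
    v <- pp
    if (a > 1) {
      Va <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Va %*% crossprod(Va, pp)
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v %*% crossprod(v, s)
    R[, a] <- r; V[, a] <- v
  }
  list(coefficients = drop(R %*% q), x_mean = x_mean, y_mean = y_mean)
}

# ordinary least squares on mean-centered data (normal equations)
ols_predict <- function(X_train, y_train, X_new) {
  n <- nrow(X_train)
  xm <- colMeans(X_train); ym <- mean(y_train)
  Xc <- X_train - rep(xm, each = n)
  b <- solve(crossprod(Xc), crossprod(Xc, y_train - ym))
  drop(ym + (X_new - rep(xm, each = nrow(X_new))) %*% b)
}
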