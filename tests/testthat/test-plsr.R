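test_that("a single component fits an exactly proportional response", {
  set.seed(2)
  # orthogonal predictor columns: y proportional to one of them is a pure
  # one-factor problem
  X <- qr.Q(qr(scale(matrix(rnorm(20 * 8), nrow = 20), scale = FALSE)))
  y <- 2.5 * X[, 3] + 4
  m <- fit_plsr(X, y, 1)
  expect_lt(sqrt(mean((predict(m, X) - y)^2)), 1e-8)
})

test_that("PLSR at full rank equals ordinary least squares", {
  set.seed(4)
  for (k in 1:5) {
    X <- matrix(rnorm(12 * 5), nrow = 12)
    y <- rnorm(12)
    m <- fit_plsr(X, y, 5)
    expect_equal(predict(m, X), ols_predict(X, y, X), tolerance = 1e-6)
  }
})

test_that("noiseless two-component mixtures are recovered exactly with A = 2", {
  set.seed(6)
  ca <- runif(15, 0, 80); cb <- runif(15, 0, 9)
  ds <- mixture_dataset(ca, cb)
  m <- fit_plsr(ds, ca, 2)
  expect_lt(sqrt(mean((predict(m, ds) - ca)^2)), 1e-6)
  # held-out noiseless mixture predicted at its true concentration
  new <- mixture_dataset(33.3, 4.4)
  expect_equal(unname(predict(m, new)), 33.3, tolerance = 1e-6)
  # predicting the mean spectrum returns the mean response
  expect_equal(drop(predict(m, matrix(m$x_mean, 1))), m$y_mean,
               tolerance = 1e-10)
})

test_that("NIPALS regression vectors match an independent SIMPLS implementation", {
  set.seed(19)
  for (k in 1:20) {
    A <- sample(1:5, 1)
    X <- matrix(rnorm(30 * 50), nrow = 30)
    y <- drop(X[, 1:3] %*% runif(3, 0.5, 2)) + rnorm(30, 0, 0.3)
    ours <- fit_plsr(X, y, A)
    oracle <- simpls_pls1(X, y, A)
    expect_equal(ours$coefficients, oracle$coefficients,
                 tolerance = 1e-6)
  }
})

test_that("structural invariants: orthogonal scores, coefficient/component agreement", {
  set.seed(23)
  X <- matrix(rnorm(25 * 30), nrow = 25)
  y <- rnorm(25)
  m <- fit_plsr(X, y, 5)
  G <- crossprod(m$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8 * max(diag(G)))
  # component-form prediction equals regression-vector prediction
  Xc <- X - rep(m$x_mean, each = 25)
  y_comp <- m$y_mean + drop(m$scores %*% m$y_loadings)
  y_coef <- predict(m, X)
  expect_equal(y_comp, y_coef, tolerance = 1e-10)
  # training RMSE non-increasing in the number of components
  rmse_a <- vapply(1:5, function(a)
    sqrt(mean((predict(m, X, ncomp = a) - y)^2)), 0)
  expect_true(all(diff(rmse_a) <= 1e-10))
})

test_that("predictions shift with y translation and scale with y scaling", {
  set.seed(31)
  X <- matrix(rnorm(20 * 10), nrow = 20)
  y <- rnorm(20)
  Xnew <- matrix(rnorm(5 * 10), nrow = 5)
  base <- predict(fit_plsr(X, y, 3), Xnew)
  expect_equal(predict(fit_plsr(X, y + 100, 3), Xnew), base + 100,
               tolerance = 1e-8)
  expect_equal(predict(fit_plsr(X, y * -3, 3), Xnew), base * -3,
               tolerance = 1e-8)
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(10 * 4), nrow = 10)
  expect_error(fit_plsr(X, rep(1, 10), 2), "zero-variance")
  expect_error(fit_plsr(X, rnorm(10), 5), "exceeds")
  # rank-1 X cannot support 2 components
  X1 <- outer(rnorm(10), rnorm(6))
  expect_error(fit_plsr(X1, X1[, 1], 3), "rank")
  m <- fit_plsr(X, rnorm(10), 2)
  expect_error(predict(m, matrix(0, 2, 7)), "variables")
})
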