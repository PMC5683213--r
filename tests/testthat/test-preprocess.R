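test_that("region selection keeps inclusive endpoints and is an identity at full range", {
  bm <- benchmark_dataset("HTS", seed = 1)$dataset
  full <- select_region(bm, min(bm$grid), max(bm$grid))
  expect_equal(full$absorbance, bm$absorbance)

  reg <- select_region(bm, 1900, 700)
  expect_equal(length(reg$grid), 601)        # (1900-700)/2 + 1 on a 2 cm-1 grid
  expect_equal(range(reg$grid), c(700, 1900))
  # water stretching/combination bands fall outside the selected region
  expect_false(any(abs(reg$grid - 3300) < 200))
  expect_false(any(abs(reg$grid - 2110) < 100))

  expect_error(select_region(bm, 100, 200), "does not intersect")
})

test_that("baseline offset subtracts the per-spectrum minimum exactly", {
  ds <- tiny_dataset(rbind(c(0.2, 0.7, 0.5), c(0, 0, 0)))
  out <- baseline_offset(ds)
  expect_equal(out$absorbance[1, ], c(0.0, 0.5, 0.3))
  expect_equal(out$absorbance[2, ], c(0, 0, 0))
  # invariance to an additive constant
  shifted <- tiny_dataset(matrix(c(0.2, 0.7, 0.5) + 3.7, nrow = 1))
  expect_equal(baseline_offset(shifted)$absorbance[1, ], c(0.0, 0.5, 0.3))
  expect_equal(apply(baseline_offset(ds)$absorbance, 1, min), c(0, 0),
               ignore_attr = TRUE)
})

test_that("Savitzky-Golay weights match the closed-form quadratic solution", {
  expect_equal(sg_coefficients(5, 2, 0), c(-3, 12, 17, 12, -3) / 35)
  # smoothing weights sum to one, derivative weights to zero
  expect_equal(sum(sg_coefficients(15, 2, 0)), 1)
  expect_equal(sum(sg_coefficients(15, 2, 2)), 0, tolerance = 1e-12)
})

test_that("Savitzky-Golay filtering reproduces polynomials and scales by spacing", {
  g <- seq(700, 1900, 2)
  # deriv 2 of a constant is zero
  const <- tiny_dataset(matrix(5, 1, length(g)), grid = g)
  expect_equal(max(abs(savitzky_golay(const, 15, 2, 2)$absorbance)), 0)
  # deriv 2 of a*nu^2 is the constant 2a, in wavenumber units
  a <- 3e-4
  quad <- tiny_dataset(matrix(a * g^2, 1), grid = g)
  d2 <- savitzky_golay(quad, 15, 2, 2)
  expect_equal(d2$absorbance[1, ], rep(2 * a, length(d2$grid)),
               tolerance = 1e-10)
  # deriv 0 with polyorder 3 reproduces a cubic exactly on interior points
  cub <- tiny_dataset(matrix(1e-6 * g^3 - 0.1 * g, 1), grid = g)
  sm <- savitzky_golay(cub, 11, 3, 0)
  keep <- g %in% sm$grid
  expect_equal(sm$absorbance[1, ], cub$absorbance[1, keep], tolerance = 1e-9)
  # edges without a full window are dropped, not padded
  expect_equal(length(sm$grid), length(g) - 10)
  expect_error(savitzky_golay(tiny_dataset(1:5, grid = c(1, 2, 4, 8, 16))),
               "uniform")
})

test_that("second derivative annihilates any linear baseline", {
  g <- seq(700, 1900, 2)
  set.seed(11)
  x <- build_pure_spectrum(band(1035, 35, 0.5), g)
  ds <- tiny_dataset(rbind(x, x + 0.3 + 0.002 * g), grid = g)
  d2 <- savitzky_golay(ds, 15, 2, 2)
  expect_equal(d2$absorbance[2, ], d2$absorbance[1, ], tolerance = 1e-10)
})

test_that("SG smoothing agrees with an independent filter implementation", {
  skip_if_not_installed("signal")
  g <- seq(0, 100, 1)
  set.seed(5)
  x <- sin(g / 7) + rnorm(length(g), 0, 0.05)
  ours <- savitzky_golay(tiny_dataset(matrix(x, 1), grid = g), 9, 2, 0)
  theirs <- signal::sgolayfilt(x, p = 2, n = 9)
  expect_equal(ours$absorbance[1, ], theirs[5:(length(g) - 4)],
               tolerance = 1e-10)
})

test_that("replicate averaging collapses the study set to 222 spectra", {
  bm <- benchmark_dataset("HTS", seed = 1)$dataset
  avg <- average_technical_replicates(bm)
  expect_equal(n_spectra(avg), 222)
  expect_true(all(is.na(avg$metadata$technical_replicate)))
  # averaging identical replicates returns the replicate itself
  q <- synthesize_dataset(mini_design(), benchmark_profiles(),
                          acq = quiet_acq())$dataset
  qa <- average_technical_replicates(q)
  first_rep <- q$absorbance[q$metadata$technical_replicate == 1, , drop = FALSE]
  expect_equal(qa$absorbance, first_rep, ignore_attr = TRUE)
})

test_that("averaging three replicates shrinks noise variance towards sigma^2/3", {
  set.seed(21)
  n_draws <- 20000
  noise <- matrix(rnorm(3 * n_draws, 0, 0.3), ncol = 3)
  avg_var <- stats::var(rowMeans(noise))
  expect_equal(avg_var, 0.09 / 3, tolerance = 0.03)
})

test_that("SNV standardises each spectrum and absorbs affine transforms", {
  set.seed(9)
  X <- matrix(rnorm(5 * 50), nrow = 5)
  ds <- tiny_dataset(X)
  out <- snv(ds)
  expect_equal(unname(rowMeans(out$absorbance)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(out$absorbance, 1, sd)), rep(1, 5), tolerance = 1e-12)
  # snv(a x + b) = sign(a) snv(x)
  ds2 <- tiny_dataset(-2.5 * X + 7)
  expect_equal(snv(ds2)$absorbance, -out$absorbance, tolerance = 1e-10)
  expect_error(snv(tiny_dataset(matrix(1, 1, 10))), "zero-variance")
})

test_that("EMSC inverts a known affine distortion exactly", {
  g <- seq(700, 1900, 2)
  r <- build_pure_spectrum(rbind(band(1035, 35, 0.5), band(1725, 40, 0.3)), g)
  u <- 2 * (g - min(g)) / (max(g) - min(g)) - 1
  distorted <- rbind(1.7 * r + 0.2 - 0.1 * u + 0.05 * u^2,
                     0.4 * r - 0.3 + 0.2 * u,
                     r)
  ds <- spectral_dataset(g, distorted, data.frame(sample_id = c("a", "b", "c")))
  out <- emsc(ds, r)
  for (i in 1:3) expect_equal(out$absorbance[i, ], r, tolerance = 1e-10)
  expect_error(emsc(ds, rep(1, length(g))), "degenerate")
})

test_that("frozen plans execute their steps in order and deterministically", {
  bm <- benchmark_dataset("HTS", seed = 1)$dataset
  hts1 <- apply_plan(bm, "hts_media")
  hts2 <- apply_plan(bm, "hts_media")
  expect_identical(hts1$absorbance, hts2$absorbance)
  expect_equal(n_spectra(hts1), 222)
  expect_equal(range(hts1$grid), c(714, 1886))   # 7 points trimmed per edge

  atr <- apply_plan(benchmark_dataset("ATR", seed = 1)$dataset, "atr_media")
  expect_equal(n_spectra(atr), 666)
  expect_equal(apply(atr$absorbance, 1, min), rep(0, 666), ignore_attr = TRUE)
})
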