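test_that("identical seeds give bit-identical datasets; different seeds differ", {
  a <- benchmark_dataset("HTS", seed = 7)
  b <- benchmark_dataset("HTS", seed = 7)
  expect_identical(a$dataset$absorbance, b$dataset$absorbance)
  expect_identical(a$reference, b$reference)
  c_ <- benchmark_dataset("HTS", seed = 8)
  expect_false(identical(a$dataset$absorbance, c_$dataset$absorbance))
})

test_that("with noise, jitter and drift off the technical replicates are bit-identical", {
  out <- synthesize_dataset(mini_design(), benchmark_profiles(),
                            acq = quiet_acq())
  ds <- out$dataset
  for (sid in unique(ds$metadata$sample_id)) {
    rows <- ds$absorbance[ds$metadata$sample_id == sid, , drop = FALSE]
    expect_identical(rows[1, ], rows[2, ])
    expect_identical(rows[1, ], rows[3, ])
  }
})

test_that("the noise-free spectrum is linear in the concentration vector", {
  lib <- default_component_library()
  acq <- quiet_acq()
  spectrum_for <- function(glc, cit) {
    profiles <- data.frame(strain = "s", temperature = 30, day = 0:1,
                           glucose = c(80, glc), citric_acid = c(0, cit))
    d <- mini_design("s", 30, days = 1, technical_replicates = 1)
    synthesize_dataset(d[d$sample_type == "supernatant", ],
                       profiles, lib, acq)$dataset$absorbance[1, ]
  }
  base <- spectrum_for(0, 0)            # background only
  set.seed(42)
  for (k in 1:5) {
    g1 <- runif(1, 0, 80); c1 <- runif(1, 0, 9)
    g2 <- runif(1, 0, 80); c2 <- runif(1, 0, 9)
    s1 <- spectrum_for(g1, c1) - base
    s2 <- spectrum_for(g2, c2) - base
    s12 <- spectrum_for(g1 + g2, c1 + c2) - base
    expect_equal(s12, s1 + s2, tolerance = 1e-12)
  }
  # Beer-Lambert doubling at the acid carbonyl band
  i1725 <- which.min(abs(acq$grid - 1725))
  c_only <- spectrum_for(0, 4) - base
  c_double <- spectrum_for(0, 8) - base
  expect_equal(c_double[i1725], 2 * c_only[i1725], tolerance = 1e-12)
})

test_that("HTS dilution scales the fingerprint-region absorbance by 1/dilution", {
  d <- mini_design(technical_replicates = 1)
  pr <- benchmark_profiles()
  diluted <- synthesize_dataset(d, pr, acq = quiet_acq(dilution_factor = 10))
  neat <- synthesize_dataset(d, pr, acq = quiet_acq(dilution_factor = 1))
  reg <- diluted$dataset$grid >= 900 & diluted$dataset$grid <= 1200
  expect_equal(rowMeans(diluted$dataset$absorbance[, reg]),
               rowMeans(neat$dataset$absorbance[, reg]) / 10,
               tolerance = 1e-12)
})

test_that("water dominates ATR spectra but not HTS spectra", {
  atr <- benchmark_dataset("ATR", seed = 3)$dataset
  peak_pos <- atr$grid[apply(atr$absorbance, 1, which.max)]
  expect_true(all(abs(peak_pos - 3300) <= 200))

  hts <- benchmark_dataset("HTS", seed = 3)$dataset
  peak_pos_h <- hts$grid[apply(hts$absorbance, 1, which.max)]
  expect_false(any(abs(peak_pos_h - 3300) <= 200))
})

test_that("end-cultivation acid and sugar peaks are of comparable magnitude", {
  # citric acid ~8.8 g/L vs glucose ~8 g/L, the end-cultivation situation in
  # which the 1725 cm-1 peak rivals the 1035 cm-1 peak
  lib <- default_component_library()
  profiles <- data.frame(strain = "s", temperature = 30, day = 0:1,
                         glucose = c(80, 8), citric_acid = c(0, 8.8))
  d <- mini_design("s", 30, days = 1, technical_replicates = 1)
  out <- synthesize_dataset(d[d$sample_type == "supernatant", ], profiles,
                            lib, quiet_acq())
  s <- out$dataset$absorbance[1, ]
  bg <- build_pure_spectrum(lib$components$background, out$dataset$grid) / 10
  s <- s - bg
  a1725 <- s[which.min(abs(out$dataset$grid - 1725))]
  a1035 <- s[which.min(abs(out$dataset$grid - 1035))]
  expect_gt(a1725 / a1035, 0.5)
  expect_lt(a1725 / a1035, 2)
})

test_that("missing components and biomass rows are rejected", {
  lib <- default_component_library()
  lib$components$citric_acid <- NULL
  lib$molar_mass <- lib$molar_mass[names(lib$molar_mass) != "citric_acid"]
  expect_error(synthesize_dataset(mini_design(), benchmark_profiles(),
                                  lib, quiet_acq()),
               "missing from library")
  db <- screening_design(include_biomass = TRUE)
  expect_error(synthesize_dataset(db, benchmark_profiles(), acq = quiet_acq()),
               "biomass")
})

test_that("reference table records true pre-dilution concentrations per sample", {
  bm <- benchmark_dataset("HTS", seed = 1)
  expect_equal(nrow(bm$reference), 222)
  expect_false(any(duplicated(bm$reference$sample_id)))
  med <- bm$reference[grepl("^med", bm$reference$sample_id), ]
  expect_equal(med$glucose, rep(80, 6))
  expect_equal(med$citric_acid, rep(0, 6))
  expect_true(max(bm$reference$citric_acid) <= 7.5)
})
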