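test_that("segments group whole conditions: 74 for the full design, 9 or 3 spectra each", {
  atr <- screening_design()                 # unaveraged: 3 wells x 3 reps
  seg_atr <- build_segments(atr)
  expect_equal(length(unique(seg_atr)), 74)
  expect_true(all(table(seg_atr) == 9))

  hts <- atr[atr$technical_replicate == 1, ]  # averaged: one spectrum/sample
  seg_hts <- build_segments(hts)
  expect_equal(length(unique(seg_hts)), 74)
  expect_true(all(table(seg_hts) == 3))

  single <- data.frame(strain = "s", temperature = 30, day = 1,
                       sample_type = "supernatant")
  expect_equal(length(unique(build_segments(single))), 1)
  expect_error(build_segments(data.frame(strain = "s")), "grouping key")
})

test_that("leave-one-segment-out CV is exact on noiseless linear data", {
  set.seed(14)
  conc <- runif(24, 0, 80)
  ds <- mixture_dataset(conc, rep(0, 24))
  segments <- as.character(rep(1:8, each = 3))
  cv <- segmented_cross_validation(ds, conc, segments, a_max = 3)
  expect_lt(cv$rmsecv[1], 1e-8)
  expect_equal(cv$n_segments, 8)
  expect_false(anyNA(cv$predictions))
})

test_that("segment-wise CV is more conservative than random splits under replicate noise", {
  # replicates within a condition share a noise component; holding out whole
  # conditions prevents that shared noise from flattering the error estimate
  set.seed(55)
  n_cond <- 15; reps <- 3; p <- 20
  seg_rmse <- rand_rmse <- numeric(50)
  for (r in 1:50) {
    y_cond <- runif(n_cond, 0, 10)
    s <- rnorm(p)
    X <- outer(rep(y_cond, each = reps), s)
    X <- X + matrix(rnorm(n_cond * p, 0, 0.8), n_cond, p)[rep(1:n_cond, each = reps), ] +
      matrix(rnorm(n_cond * reps * p, 0, 0.1), n_cond * reps, p)
    y <- rep(y_cond, each = reps)
    segs <- as.character(rep(1:n_cond, each = reps))
    cv_seg <- segmented_cross_validation(X, y, segs, a_max = 2)
    cv_rand <- segmented_cross_validation(X, y, sample(segs), a_max = 2)
    seg_rmse[r] <- min(cv_seg$rmsecv)
    rand_rmse[r] <- min(cv_rand$rmsecv)
  }
  expect_gt(mean(seg_rmse), mean(rand_rmse))
})

test_that("independent-test splits isolate a whole strain x temperature condition", {
  atr <- screening_design()
  sp_atr <- independent_test_split(atr, "P_glabrum", 30)
  expect_equal(length(sp_atr$test), 108)
  expect_equal(length(sp_atr$train), 666 - 108)

  hts <- atr[atr$technical_replicate == 1, ]
  sp_hts <- independent_test_split(hts, "P_glabrum", 30)
  expect_equal(length(sp_hts$test), 36)

  # glucose convention: media out of the training set
  sp_g <- independent_test_split(atr, "P_glabrum", 30, include_media = FALSE)
  expect_equal(length(sp_g$train), 540)

  none <- independent_test_split(atr, NULL, NULL)
  expect_equal(length(none$test), 0)
  expect_equal(length(none$train), nrow(atr))
  expect_error(independent_test_split(atr, "no_such_strain", 30), "not present")
})

test_that("workflow restricts strains per analyte and reproduces the training arithmetic", {
  bm <- benchmark_dataset("ATR", seed = 1)
  rep_c <- run_calibration_workflow(bm$dataset, bm$reference, "citric_acid",
                                    "ATR", scheme = c("CV", "ITV"))
  # only producer supernatants + media remain: 216 + 18 spectra
  expect_equal(rep_c$n_spectra, 234)
  expect_equal(rep_c$schemes$ITV$n_train, 126)   # 108 at 20 C + 18 media
  expect_equal(rep_c$schemes$ITV$n_test, 108)

  rep_g <- run_calibration_workflow(bm$dataset, bm$reference, "glucose",
                                    "ATR", scheme = c("CV", "ITV"))
  expect_equal(rep_g$n_spectra, 666)
  expect_equal(rep_g$schemes$CV$n_segments, 74)
  expect_equal(rep_g$schemes$ITV$n_train, 540)   # media excluded for glucose
  expect_equal(rep_g$schemes$ITV$n_test, 108)

  expect_error(run_calibration_workflow(bm$dataset,
                                        bm$reference[, 1:2, drop = FALSE],
                                        "citric_acid", "ATR"),
               "absent")
})

test_that("HTS workflow counts match the averaged design", {
  bm <- benchmark_dataset("HTS", seed = 1)
  rep_g <- run_calibration_workflow(bm$dataset, bm$reference, "glucose", "HTS",
                                    scheme = c("CV", "ITV"))
  expect_equal(rep_g$n_spectra, 222)
  expect_equal(rep_g$schemes$CV$n_segments, 74)
  expect_equal(rep_g$schemes$ITV$n_train, 180)
  expect_equal(rep_g$schemes$ITV$n_test, 36)
  rep_c <- run_calibration_workflow(bm$dataset, bm$reference, "citric_acid",
                                    "HTS", scheme = "ITV")
  expect_equal(rep_c$schemes$ITV$n_train, 42)
  expect_equal(rep_c$schemes$ITV$n_test, 36)
})

test_that("a noise-free dataset calibrates essentially perfectly", {
  out <- synthesize_dataset(screening_design(technical_replicates = 1),
                            benchmark_profiles(), acq = quiet_acq())
  rep_g <- run_calibration_workflow(out$dataset, out$reference, "glucose",
                                    "HTS", scheme = "CV", a_max = 4)
  expect_gt(rep_g$schemes$CV$metrics$r2, 0.999)
})

test_that("report metrics recompute from the stored per-sample predictions", {
  bm <- benchmark_dataset("HTS", seed = 2)
  rep_g <- run_calibration_workflow(bm$dataset, bm$reference, "glucose", "HTS",
                                    scheme = "CV")
  p <- rep_g$schemes$CV$predictions
  again <- compute_metrics(p$y_true, p$y_pred, rep_g$reference_scale)
  expect_identical(again$rmse, rep_g$schemes$CV$metrics$rmse)
  expect_identical(again$r2, rep_g$schemes$CV$metrics$r2)
  # fold membership respects conditions: a segment never splits
  expect_true(all(tapply(p$segment, paste(p$sample_id), function(s)
    length(unique(s))) == 1))
})
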