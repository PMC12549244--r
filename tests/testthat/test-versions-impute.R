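test_that("the eight baseline versions follow their formulas", {
  expect_equal(apply_feature_version(10, pretrial_b = 8, version = 1), 2)
  expect_equal(apply_feature_version(10, pretrial_b = 8, version = 4), 1.25)
  expect_equal(apply_feature_version(10, mean_pretrial_b = 4, version = 2), 6)
  expect_equal(apply_feature_version(10, mean_pretrial_b = 4, version = 5), 2.5)
  # participant series {1, 2, 3}, active value 3: mu = 2, sigma = 1
  expect_equal(apply_feature_version(3, participant_mean = 2,
                                     participant_sd = 1, version = 7), 1)
  expect_equal(apply_feature_version(3, participant_mean = 2, version = 8), 1)
  # identity case: active equals the pre-experimental baseline
  expect_equal(apply_feature_version(7, preexp_b = 7, version = 3), 0)
  expect_equal(apply_feature_version(7, preexp_b = 7, version = 6), 1)
  # degenerate denominators flag missing, never Inf
  expect_true(is.na(apply_feature_version(5, pretrial_b = 0, version = 4)))
  expect_true(is.na(apply_feature_version(5, participant_mean = 5,
                                          participant_sd = 0, version = 7)))
  expect_error(apply_feature_version(1, version = 9), "1..8")
})

test_that("design matrix assembly yields 1,774 predictors with version identities", {
  feats <- small_feats()
  fm <- build_design_matrix(feats)
  expect_equal(ncol(fm$X) - 4L, 1774L)
  expect_equal(nrow(fm$X), nrow(feats$features))
  expect_equal(length(fm$y), nrow(fm$X))

  # v3 = a - b_preexp and v6 = a / b_preexp are consistent per epoch
  a <- feats$features$ecg_rr_mean
  pexp <- feats$preexp
  be <- pexp$ecg_rr_mean[match(paste(feats$features$participant,
                                     feats$features$session),
                               paste(pexp$participant, pexp$session))]
  expect_equal(fm$X$ecg_rr_mean_v3, a - be)
  expect_equal(fm$X$ecg_rr_mean_v6, a / be)

  # v7 standardizes within participant: mean 0, sd 1 over its epochs
  v7 <- fm$X$ecg_rr_mean_v7[fm$X$participant == 1]
  expect_lt(abs(mean(v7, na.rm = TRUE)), 1e-10)
  expect_equal(sd(v7, na.rm = TRUE), 1, tolerance = 1e-10)

  # train-only participant statistics differ from the all-data ones
  train <- feats$features[feats$features$trial != 1,
                          c("participant", "session", "trial", "epoch")]
  fm_tr <- build_design_matrix(feats, train_keys = train)
  expect_false(isTRUE(all.equal(fm$X$ecg_rr_mean_v7, fm_tr$X$ecg_rr_mean_v7)))
  v7_tr <- fm_tr$X$ecg_rr_mean_v7[fm_tr$X$participant == 1 &
                                    fm_tr$X$trial != 1]
  expect_lt(abs(mean(v7_tr, na.rm = TRUE)), 1e-10)
})

test_that("hierarchical imputation follows trial -> session -> other-sessions", {
  keys <- tidyr::expand_grid(participant = 1L, session = 1:2, trial = 1:2,
                             epoch = 1:8)
  X <- matrix(NA_real_, nrow(keys), 2,
              dimnames = list(NULL, c("f1", "f2")))
  X[, "f1"] <- seq(2, by = 2, length.out = nrow(keys))
  X[, "f2"] <- 1
  # epoch 3 of (s1, t1) missing: trial-mates are {2,4,6,8,10,12,14,16}\{6}
  X[3, "f1"] <- NA
  fm <- manual_matrix(keys, X)
  out <- impute_missing(fm)
  donors <- seq(2, 16, by = 2)[-3]
  expect_equal(out$X$f1[3], mean(donors))
  expect_equal(unname(out$imputed[3, "f1"]), 1L)

  # whole trial missing: session-mates (the other trial) supply the mean
  X2 <- X
  X2[keys$session == 1 & keys$trial == 1, "f1"] <- NA
  out2 <- impute_missing(manual_matrix(keys, X2))
  sess_mean <- mean(X2[keys$session == 1 & keys$trial == 2, "f1"])
  expect_true(all(out2$X$f1[keys$session == 1 & keys$trial == 1] ==
                    sess_mean))
  expect_true(all(out2$imputed[keys$session == 1 & keys$trial == 1,
                               "f1"] == 2L))

  # whole session missing: the participant's other session supplies it
  X3 <- X
  X3[keys$session == 1, "f1"] <- NA
  out3 <- impute_missing(manual_matrix(keys, X3))
  other_mean <- mean(X3[keys$session == 2, "f1"])
  expect_true(all(out3$X$f1[keys$session == 1] == other_mean))
  expect_true(all(out3$imputed[keys$session == 1, "f1"] == 3L))
})

test_that("imputation is idempotent, preserves observations, errors without donors", {
  fm <- small_matrix()
  once <- fm
  twice <- impute_missing(once)
  expect_identical(once$X, twice$X)

  # observed cells never modified
  raw <- build_design_matrix(small_feats())
  Xr <- as.matrix(raw$X[, -(1:4)])
  Xi <- as.matrix(fm$X[, -(1:4)])
  obs <- !is.na(Xr)
  expect_identical(Xr[obs], Xi[obs])
  expect_false(anyNA(Xi))
  expect_true(all(fm$imputed[obs] == 0L))

  # a fully absent matrix column has no donor without the population fallback
  keys <- tidyr::expand_grid(participant = 1:2, session = 1L, trial = 1:2,
                             epoch = 1:2)
  X <- matrix(1, nrow(keys), 2, dimnames = list(NULL, c("f1", "f2")))
  X[keys$participant == 1, "f1"] <- NA
  expect_error(impute_missing(manual_matrix(keys, X),
                              population_fallback = FALSE),
               "no imputation donor for feature 'f1'")
  ok <- impute_missing(manual_matrix(keys, X))
  expect_true(all(ok$X$f1[keys$participant == 1] == 1))
  expect_true(all(ok$imputed[keys$participant == 1, "f1"] == 4L))

  # untouched matrix passes through bit-for-bit
  clean <- manual_matrix(keys, matrix(rnorm(nrow(keys) * 2), ncol = 2,
                                      dimnames = list(NULL, c("f1", "f2"))))
  expect_identical(impute_missing(clean)$X[, -(1:4)], clean$X[, -(1:4)])
})
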