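test_that("LOTOPS splitting withholds one trial per participant-session", {
  d <- study_design()  # default protocol
  sch <- lotops_split(d, seed = 3)
  expect_equal(nrow(sch), 48L)  # 12 participants x 4 sessions
  expect_true(all(sch$withheld_trial %in% 1:6))
  idx <- tidyr::expand_grid(participant = 1:12, session = 1:4,
                            trial = 1:6, epoch = 1:8)
  test_sel <- trustdyn:::is_test_epoch(idx, sch)
  expect_equal(sum(test_sel), 384L)          # 48 trials x 8 epochs
  expect_equal(mean(test_sel), 1 / 6)        # exactly 1/6 of the data
  expect_identical(sch, lotops_split(d, seed = 3))
  expect_false(identical(sch$withheld_trial,
                         lotops_split(d, seed = 4)$withheld_trial))
  expect_error(lotops_split(study_design(n_trials = 1)), "2 trials")
})

test_that("metrics: RMSE, median absolute error, and Q^2", {
  m0 <- compute_metrics(c(0.2, 0.8, 0.5), c(0.2, 0.8, 0.5))
  expect_equal(m0$rmse, 0)
  expect_equal(m0$mae, 0)
  expect_equal(m0$q2, 1)
  m1 <- compute_metrics(c(0, 1), c(0.5, 0.5))
  expect_equal(m1$rmse, 0.5)
  expect_equal(m1$mae, 0.5)
  # MAE is the *median* absolute error
  m2 <- compute_metrics(c(0.1, 0.2, 0.9), c(0, 0, 0))
  expect_equal(m2$mae, 0.2)
  expect_equal(m2$rmse, sqrt((0.01 + 0.04 + 0.81) / 3), tolerance = 1e-6)
  expect_equal(m2$rmse, 0.5354, tolerance = 1e-3)
  expect_error(compute_metrics(1, numeric(0)), "equal length")
})

test_that("MCCV report structure: partitions, rows, and reproducible summary", {
  mccv <- small_mccv()
  expect_s3_class(mccv, "trust_mccv")
  expect_equal(nrow(mccv$splits), 2L)
  expect_named(mccv$splits, c("split", "adj_r2", "model_q2", "test_q2",
                              "rmse", "mae", "predictors", "capped"))
  # summary mean row equals the arithmetic mean of the split rows
  means <- colMeans(mccv$splits[, -1])
  smean <- unlist(mccv$summary[mccv$summary$stat == "mean", -1])
  expect_equal(unname(smean), unname(means), tolerance = 1e-12)

  # every epoch is in exactly one partition per split
  feats <- small_feats()
  for (sch in mccv$schemes) {
    test_sel <- trustdyn:::is_test_epoch(feats$index, sch)
    expect_equal(sum(test_sel) + sum(!test_sel), nrow(feats$index))
    expect_equal(mean(test_sel), 1 / small_design()$n_trials)
  }
  # stored predictions cover the report split's withheld epochs, capped
  expect_equal(nrow(mccv$predictions),
               sum(trustdyn:::is_test_epoch(feats$index,
                                            mccv$schemes[[2]])))
  expect_true(all(mccv$predictions$.pred >= 0 & mccv$predictions$.pred <= 1))
  expect_equal(nrow(mccv$per_participant_rmse), 2L)
  expect_equal(tidy(mccv), mccv$splits)
})

test_that("label permutation destroys test performance (leakage canary)", {
  mccv <- small_mccv()
  pr <- mccv$predictions
  set.seed(9)
  perm_q2 <- replicate(20, {
    yp <- sample(pr$y)
    1 - sum((yp - pr$.pred)^2) / sum((yp - mean(pr$y))^2)
  })
  expect_lte(median(perm_q2), 0.1)
})

test_that("descriptive model reports retention by feature category", {
  cfg <- selection_config(n_reps_round1 = 2, n_reps_round2 = 2,
                          nlambda = 30, seed = 5)
  desc <- fit_descriptive(small_feats(), cfg, max_p_fraction = 1,
                          q2_tolerance = Inf)
  expect_s3_class(desc, "trust_descriptive")
  expect_setequal(desc$retention$category,
                  c("ecg", "eda", "rsp", "eeg", "fnirs", "eye",
                    "embedded", "background"))
  expect_equal(sum(desc$retention$created), 1774L)
  expect_equal(sum(desc$retention$retained), desc$model$p)
  expect_true(all(desc$retention$pct_retained >= 0 &
                    desc$retention$pct_retained <= 100))
  expect_gt(desc$metrics$adj_r2, 0.3)
})

test_that("figures build from MCCV predictions", {
  mccv <- small_mccv()
  p1 <- plot_trust_traces(mccv)
  expect_s3_class(p1, "ggplot")
  b1 <- ggplot2::ggplot_build(p1)
  expect_equal(length(unique(b1$layout$layout$PANEL)), 2L)  # 2 participants
  p2 <- ggplot2::autoplot(mccv)
  expect_s3_class(p2, "ggplot")
})
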