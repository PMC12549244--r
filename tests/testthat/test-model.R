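test_that("OLS refit matches the normal-equations oracle to 1e-8", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(10:50, 1)
    p <- sample(2:5, 1)
    X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("x", 1:p)))
    y <- rnorm(n)
    m <- fit_ols(X, y)
    Xi <- cbind(1, X)
    oracle <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
    expect_equal(unname(m$coefficients), as.numeric(oracle),
                 tolerance = 1e-8)
    # adjusted R^2 identity
    expect_equal(m$adj_r2, 1 - (1 - m$r2) * (n - 1) / (n - p - 1))
  }
})

test_that("OLS handles exact fits and collinear duplicates", {
  set.seed(2)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 0.2 + X %*% c(1, -2, 0.5)
  m <- fit_ols(X, as.numeric(y))
  expect_equal(m$r2, 1, tolerance = 1e-12)
  expect_lt(max(abs(as.numeric(y) - m$fitted)), 1e-10)

  Xd <- cbind(X, d = X[, "a"])  # exact duplicate
  w <- testthat::capture_warnings(
    md <- fit_ols(Xd, as.numeric(y) + rnorm(20, 0, 0.1)))
  expect_true(any(grepl("collinear", w)))
  expect_equal(md$p, 3L)
  suppressWarnings(
    expect_error(fit_ols(X[1:3, ], y[1:3]), "n > p \\+ 1"))

  td <- tidy(m)
  expect_equal(td$term[1], "(Intercept)")
  expect_equal(nrow(td), 4L)
  gl <- glance(m)
  expect_equal(gl$p, 3L)
})

test_that("stability selection finds a planted predictor and stays sparse under the null", {
  set.seed(10)
  n <- 500
  X <- matrix(rnorm(n * 201), n,
              dimnames = list(NULL, c("signal", paste0("noise", 1:200))))
  y <- X[, "signal"] + rnorm(n)
  cfg <- selection_config(n_reps_round1 = 5, n_reps_round2 = 5,
                          nlambda = 50, seed = 2)
  sel <- lasso_stability_select(X, y, cfg)
  hit <- vapply(sel$round2_sets, function(s) "signal" %in% s, logical(1))
  expect_gte(mean(hit), 0.9)

  # independent response: 1-SE sets stay near-empty
  null_sizes <- unlist(lapply(1:20, function(s) {
    set.seed(100 + s)
    Xn <- matrix(rnorm(120 * 60), 120)
    colnames(Xn) <- paste0("x", 1:60)
    yn <- rnorm(120)
    cfgn <- selection_config(n_reps_round1 = 2, n_reps_round2 = 2,
                             nlambda = 30, seed = s)
    lengths(lasso_stability_select(Xn, yn, cfgn)$round2_sets)
  }))
  expect_lte(median(null_sizes), 2)

  expect_error(lasso_stability_select(X, rep(1, n), cfg), "constant")
  expect_error(lasso_stability_select(matrix(1, 50, 3), rnorm(50), cfg),
               "constant")
})

test_that("round 1 records 50 x 2 sets under the default repetition count", {
  set.seed(3)
  X <- matrix(rnorm(60 * 10), 60, dimnames = list(NULL, paste0("x", 1:10)))
  y <- X[, 1] - X[, 2] + rnorm(60, 0, 0.5)
  sel <- lasso_stability_select(X, y, selection_config(nlambda = 30, seed = 4))
  expect_equal(nrow(sel$round1), 100L)
  expect_equal(sum(sel$round1$rule == "1se"), 50L)
  expect_equal(sum(sel$round1$rule == "min"), 50L)
  expect_length(sel$round2_sets, 50L)
  # monotone penalty: the 1-SE support never exceeds the min-MSE support
  by_rep <- split(sel$round1, sel$round1$rep)
  for (r in by_rep) {
    s1 <- r$set[r$rule == "1se"][[1]]
    sm <- r$set[r$rule == "min"][[1]]
    expect_lte(length(s1), length(sm))
  }
})

test_that("LOTO Q^2 matches a hand-rolled oracle and its limiting cases", {
  set.seed(4)
  n_tr <- 8; per <- 6
  trial <- rep(seq_len(n_tr), each = per)
  X <- matrix(rnorm(n_tr * per * 2), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  y <- plogis(X %*% c(1, -1) + rnorm(n_tr * per, 0, 0.3))[, 1]
  q2 <- loto_q2(X, y, trial_id = trial)
  # oracle: explicit per-trial refits
  press <- 0
  for (tr in unique(trial)) {
    hold <- trial == tr
    f <- lm.fit(cbind(1, X[!hold, ]), y[!hold])
    pred <- pmin(pmax(cbind(1, X[hold, ]) %*% f$coefficients, 0), 1)
    press <- press + sum((y[hold] - pred)^2)
  }
  expect_equal(q2, 1 - press / sum((y - mean(y))^2), tolerance = 1e-12)

  y_lin <- pmin(pmax(0.5 + 0.2 * X[, "a"] - 0.1 * X[, "b"], 0), 1)
  expect_gte(loto_q2(X, y_lin, trial_id = trial), 0.99)
  expect_lt(abs(loto_q2(X, y, trial_id = trial,
                        predictors = character(0))), 0.1)
  expect_error(loto_q2(X, y, trial_id = rep(1, length(y))), "2 trials")
})

test_that("model selection enforces both anti-overfitting constraints", {
  fake <- function(id, p, adj, q2) {
    tibble::tibble(set_id = id, predictors = list(paste0("x", seq_len(p))),
                   p = p, adj_r2 = adj, loto_q2 = q2,
                   model = list(structure(
                     list(adj_r2 = adj, loto_q2 = q2, p = p,
                          predictors = paste0("x", seq_len(p)),
                          coefficients = c(`(Intercept)` = 0.5)),
                     class = "trust_model")))
  }
  cand <- dplyr::bind_rows(
    fake(1, 400, 0.95, 0.90),   # p = 400 > 1920 / 5 = 384: eliminated
    fake(2, 10, 0.90, 0.60),    # gap 0.3 > 0.2: eliminated
    fake(3, 12, 0.80, 0.70),
    fake(4, 15, 0.83, 0.75))
  win <- select_model(cand, n_obs = 1920)
  expect_equal(win$adj_r2, 0.83)
  info <- attr(win, "selection")
  expect_true(info$eliminated[info$set_id == 1])
  expect_true(info$eliminated[info$set_id == 2])
  expect_error(select_model(dplyr::bind_rows(fake(1, 400, 0.95, 0.90)),
                            n_obs = 1920), "violate")
  # ties break toward fewer predictors
  tie <- dplyr::bind_rows(fake(1, 5, 0.8, 0.75), fake(2, 3, 0.8, 0.75))
  expect_equal(select_model(tie, n_obs = 1000)$p, 3)
})

test_that("trust predictions are capped to the slider range with a count", {
  model <- structure(
    list(coefficients = c(`(Intercept)` = 0, x = 1), predictors = "x",
         n = 10L, p = 1L, r2 = 1, adj_r2 = 1, sigma = 0,
         loto_q2 = NA_real_),
    class = "trust_model")
  Xn <- matrix(c(1.3, -0.2, 0.5), ncol = 1, dimnames = list(NULL, "x"))
  pr <- predict_trust(model, Xn)
  expect_equal(pr$.pred, c(1, 0, 0.5))
  expect_equal(pr$.raw, c(1.3, -0.2, 0.5))
  expect_equal(sum(pr$.capped), 2L)
  expect_error(predict_trust(model, matrix(1, 2, 1,
                                           dimnames = list(NULL, "z"))),
               "missing predictor")
})
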