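# Model-building engine: two-round relaxed-LASSO stability selection,
# OLS refit, adjusted R^2, exhaustive leave-one-trial-out Q^2,
# anti-overfitting constraints, and bounded prediction.

#' Selection configuration
#'
#' Controls the two-round stability selection: round 1 runs
#' `n_reps_round1` 10-fold cross-validated LASSO fits and records the
#' support at both the 1-SE and minimum-MSE lambda; round 2 reruns
#' `n_reps_round2` fits on the union of round-1 features, keeping the 1-SE
#' support of each.
#'
#' @param n_reps_round1,n_reps_round2 Repetition counts (defaults 50).
#' @param cv_folds Cross-validation folds for the lambda path (default 10).
#' @param nlambda Lambda grid size.
#' @param lambda_min_ratio Smallest lambda as a fraction of lambda_max.
#' @param seed Integer seed for fold assignment.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(n_reps_round1 = 50L, n_reps_round2 = 50L,
                             cv_folds = 10L, nlambda = 100L,
                             lambda_min_ratio = 1e-3, seed = 1L) {
  assert_that(cv_folds >= 2, "cv_folds must be at least 2")
  assert_that(n_reps_round1 >= 1 && n_reps_round2 >= 1,
              "repetition counts must be at least 1")
  structure(list(n_reps_round1 = as.integer(n_reps_round1),
                 n_reps_round2 = as.integer(n_reps_round2),
                 cv_folds = as.integer(cv_folds),
                 nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio,
                 seed = as.integer(seed)),
            class = "selection_config")
}

as_predictor_matrix <- function(X) {
  if (inherits(X, "trust_matrix")) {
    assert_that(!is.null(X$imputed),
                "design matrix must be imputed before model fitting")
    as.matrix(select(X$X, -(1:4)))
  } else {
    as.matrix(X)
  }
}

support_of <- function(cvfit, s) {
  cf <- coef(cvfit, s = s)
  rownames(cf)[which(cf[, 1] != 0)] |> setdiff("(Intercept)")
}

#' Two-round relaxed-LASSO stability selection
#'
#' Round 1: `n_reps_round1` repetitions of 10-fold cross-validated LASSO
#' with re-randomized folds, recording the support at both the 1-SE and the
#' minimum-MSE lambda (up to `2 * n_reps_round1` recorded sets; unique sets
#' retained).  Round 2: the union of all retained features is offered to
#' `n_reps_round2` further repetitions, keeping the 1-SE support of each —
#' these are the candidate predictor sets handed to the OLS refit.
#'
#' @param X A `trust_matrix` (imputed) or numeric predictor matrix.
#' @param y Response vector (ignored when `X` is a `trust_matrix`).
#' @param config A [selection_config()].
#' @return An object of class `stability_selection`: list with `round1`
#'   (tibble: rep, rule, set), `unique_sets`, `union_features`, and
#'   `round2_sets` (list of candidate predictor-name sets).
#' @export
lasso_stability_select <- function(X, y = NULL, config = selection_config()) {
  if (inherits(X, "trust_matrix")) y <- X$y
  Xm <- as_predictor_matrix(X)
  n <- nrow(Xm)
  assert_that(sd(y) > 0, "constant response: nothing to model")
  col_sd <- apply(Xm, 2, sd)
  assert_that(any(col_sd > 0), "all predictors are constant")
  assert_that(n >= config$cv_folds, "need at least cv_folds observations")

  run_cv <- function(Xin, rep_seed) {
    foldid <- with_seed(rep_seed,
                        sample(rep_len(seq_len(config$cv_folds), n)))
    glmnet::cv.glmnet(Xin, y, foldid = foldid, nlambda = config$nlambda,
                      lambda.min.ratio = config$lambda_min_ratio,
                      standardize = TRUE)
  }

  r1 <- purrr::map(seq_len(config$n_reps_round1), function(r) {
    cvfit <- run_cv(Xm, child_seed(config$seed, "r1", r))
    list(
      tibble(rep = r, rule = "1se",
             set = list(support_of(cvfit, "lambda.1se"))),
      tibble(rep = r, rule = "min",
             set = list(support_of(cvfit, "lambda.min")))
    )
  })
  round1 <- purrr::list_rbind(purrr::list_flatten(r1))
  sigs <- vapply(round1$set, function(s) paste(sort(s), collapse = ","),
                 character(1))
  unique_sets <- round1$set[!duplicated(sigs)]
  union_features <- sort(unique(unlist(round1$set)))

  if (length(union_features) == 0L) {
    round2_sets <- rep(list(character(0)), config$n_reps_round2)
  } else {
    X2 <- Xm[, union_features, drop = FALSE]
    round2_sets <- purrr::map(seq_len(config$n_reps_round2), function(r) {
      if (ncol(X2) < 2L) return(union_features)  # glmnet needs >= 2 columns
      cvfit <- run_cv(X2, child_seed(config$seed, "r2", r))
      support_of(cvfit, "lambda.1se")
    })
  }
  structure(list(round1 = round1, unique_sets = unique_sets,
                 union_features = union_features,
                 round2_sets = round2_sets, config = config),
            class = "stability_selection")
}

#' @export
print.stability_selection <- function(x, ...) {
  cat("<stability_selection> round 1: ", nrow(x$round1), " recorded sets (",
      length(x$unique_sets), " unique); union ",
      length(x$union_features), " features; round 2: ",
      length(x$round2_sets), " candidate sets\n", sep = "")
  invisible(x)
}

#' Fit an OLS trust model on a predictor subset
#'
#' Ordinary least squares with intercept.  Exactly collinear (rank-deficient)
#' predictors are dropped with a warning and the model refit on the
#' remainder.
#'
#' @param X A `trust_matrix` or numeric matrix.
#' @param y Response (ignored for a `trust_matrix`).
#' @param predictors Character vector of predictor columns (default: all).
#' @return An object of class `trust_model` with named `coefficients`
#'   (including `(Intercept)`), `predictors`, `n`, `p`, `r2`, `adj_r2`,
#'   `sigma`, and `fitted`.
#' @export
fit_ols <- function(X, y = NULL, predictors = NULL) {
  if (inherits(X, "trust_matrix")) y <- X$y
  Xm <- as_predictor_matrix(X)
  predictors <- predictors %||% colnames(Xm)
  missing_cols <- setdiff(predictors, colnames(Xm))
  assert_that(length(missing_cols) == 0L,
              paste("predictors absent from matrix:",
                    paste(head(missing_cols, 3), collapse = ", ")))
  n <- length(y)
  Xs <- cbind(`(Intercept)` = 1, Xm[, predictors, drop = FALSE])
  qr_ <- qr(Xs)
  while (qr_$rank < ncol(Xs)) {
    keep_idx <- qr_$pivot[seq_len(qr_$rank)]
    dropped <- setdiff(colnames(Xs), colnames(Xs)[keep_idx])
    warn(paste("dropping collinear predictor(s):",
               paste(head(dropped, 5), collapse = ", ")))
    predictors <- setdiff(colnames(Xs)[keep_idx], "(Intercept)")
    Xs <- cbind(`(Intercept)` = 1, Xm[, predictors, drop = FALSE])
    qr_ <- qr(Xs)
  }
  p <- length(predictors)
  assert_that(n > p + 1, "need n > p + 1 observations for OLS")
  beta <- qr.coef(qr_, y)
  fitted <- as.numeric(Xs %*% beta)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  structure(list(coefficients = beta, predictors = predictors,
                 n = n, p = p, r2 = r2, adj_r2 = adj_r2,
                 sigma = sqrt(rss / max(n - p - 1, 1)),
                 fitted = fitted, loto_q2 = NA_real_),
            class = "trust_model")
}

#' @export
print.trust_model <- function(x, ...) {
  cat("<trust_model> ", x$p, " predictors, n = ", x$n,
      ", adj R^2 = ", round(x$adj_r2, 3),
      if (is.finite(x$loto_q2)) paste0(", LOTO Q^2 = ", round(x$loto_q2, 3)),
      "\n", sep = "")
  invisible(x)
}

#' @rdname fit_ols
#' @param x A `trust_model`.
#' @param ... Unused.
#' @export
tidy.trust_model <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = as.numeric(x$coefficients))
}

#' @rdname fit_ols
#' @export
glance.trust_model <- function(x, ...) {
  tibble(r.squared = x$r2, adj.r.squared = x$adj_r2,
         loto.q.squared = x$loto_q2, sigma = x$sigma,
         n = x$n, p = x$p)
}

#' Predict trust with bounded outputs
#'
#' Linear prediction clipped to the `[0, 1]` trust-slider range; the raw
#' (uncapped) prediction is kept for diagnostics.
#'
#' @param model A `trust_model`.
#' @param X_new A `trust_matrix` or numeric matrix containing all model
#'   predictors.
#' @return Tibble with `.raw`, `.pred` (capped), and `.capped` (logical);
#'   `sum(.capped)` is the capped-prediction count.
#' @export
predict_trust <- function(model, X_new) {
  Xm <- if (inherits(X_new, "trust_matrix")) {
    as.matrix(select(X_new$X, -(1:4)))
  } else {
    as.matrix(X_new)
  }
  missing_cols <- setdiff(model$predictors, colnames(Xm))
  assert_that(length(missing_cols) == 0L,
              paste("missing predictor column(s):",
                    paste(head(missing_cols, 3), collapse = ", ")))
  raw <- as.numeric(model$coefficients[1] +
                      Xm[, model$predictors, drop = FALSE] %*%
                      model$coefficients[-1])
  pred <- clamp(raw, 0, 1)
  tibble(.raw = raw, .pred = pred, .capped = raw < 0 | raw > 1)
}

#' Exhaustive leave-one-trial-out Q^2
#'
#' For every trial in the training data, an OLS model on the given
#' predictors is fit on all other trials and used to predict the held-out
#' trial's epochs (capped to `[0, 1]`).
#' `Q^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)` with the mean taken
#' over the full training partition.
#'
#' @param X A `trust_matrix` or numeric matrix.
#' @param y Response (ignored for a `trust_matrix`).
#' @param trial_id Per-row trial grouping (ignored for a `trust_matrix`,
#'   which uses participant/session/trial).
#' @param predictors Predictor subset.
#' @return The Q^2 value.
#' @export
loto_q2 <- function(X, y = NULL, trial_id = NULL, predictors = NULL) {
  if (inherits(X, "trust_matrix")) {
    y <- X$y
    trial_id <- paste(X$X$participant, X$X$session, X$X$trial)
  }
  Xm <- as_predictor_matrix(X)
  predictors <- predictors %||% colnames(Xm)
  assert_that(length(unique(trial_id)) >= 2L,
              "loto_q2 needs at least 2 trials")
  missing_cols <- setdiff(predictors, colnames(Xm))
  assert_that(length(missing_cols) == 0L,
              paste("predictors absent from matrix:",
                    paste(head(missing_cols, 3), collapse = ", ")))
  Xs <- cbind(1, Xm[, predictors, drop = FALSE])
  press <- 0
  for (tr in unique(trial_id)) {
    hold <- trial_id == tr
    fit <- .lm.fit(Xs[!hold, , drop = FALSE], y[!hold])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    pred <- clamp(as.numeric(Xs[hold, , drop = FALSE] %*% beta), 0, 1)
    press <- press + sum((y[hold] - pred)^2)
  }
  1 - press / sum((y - mean(y))^2)
}

#' Evaluate candidate predictor sets
#'
#' Refits each candidate set with OLS and computes its adjusted R^2 and
#' leave-one-trial-out Q^2.
#'
#' @param fm An imputed `trust_matrix`.
#' @param sets List of predictor-name sets (e.g.
#'   `lasso_stability_select()$round2_sets`).
#' @return Tibble with `set_id`, `predictors` (list), `p`, `adj_r2`,
#'   `loto_q2`, and `model` (list of `trust_model`).
#' @export
evaluate_candidates <- function(fm, sets) {
  stopifnot(inherits(fm, "trust_matrix"))
  rows <- purrr::imap(sets, function(s, i) {
    if (length(s) == 0L) {
      m <- intercept_only_model(fm$y)
      q2 <- 0
    } else {
      m <- suppressWarnings(fit_ols(fm, predictors = s))
      q2 <- loto_q2(fm, predictors = m$predictors)
    }
    m$loto_q2 <- q2
    tibble(set_id = i, predictors = list(m$predictors), p = m$p,
           adj_r2 = m$adj_r2, loto_q2 = q2, model = list(m))
  })
  purrr::list_rbind(rows)
}

intercept_only_model <- function(y) {
  n <- length(y)
  structure(list(coefficients = c(`(Intercept)` = mean(y)),
                 predictors = character(0), n = n, p = 0L,
                 r2 = 0, adj_r2 = 0, sigma = sd(y),
                 fitted = rep(mean(y), n), loto_q2 = NA_real_),
            class = "trust_model")
}

#' Select the final model under anti-overfitting constraints
#'
#' Candidates are eliminated when (1) their predictor count exceeds 1/5 of
#' the training observations or (2) their LOTO Q^2 departs from the
#' adjusted R^2 by more than 0.2.  Among survivors the highest adjusted R^2
#' wins; ties break toward fewer predictors, then lexicographic predictor
#' order.
#'
#' @param candidates A tibble from [evaluate_candidates()].
#' @param n_obs Training observation count.
#' @param max_p_fraction Predictor-count cap as a fraction of `n_obs`
#'   (default 1/5, the full-scale calibration; at strongly reduced problem
#'   sizes stability selection can return well-validated sets above n/5 and
#'   the cap may be relaxed explicitly).
#' @param q2_tolerance Maximum allowed `|adj R^2 - LOTO Q^2|` (default 0.2).
#' @return The winning `trust_model`, with attribute `"selection"` carrying
#'   the constraint bookkeeping.
#' @export
select_model <- function(candidates, n_obs, max_p_fraction = 0.2,
                         q2_tolerance = 0.2) {
  assert_that(nrow(candidates) >= 1L, "no candidate models")
  cand <- candidates |>
    mutate(over_p = .data$p > n_obs * max_p_fraction,
           q2_gap = abs(.data$adj_r2 - .data$loto_q2),
           over_gap = .data$q2_gap > q2_tolerance,
           eliminated = .data$over_p | .data$over_gap)
  surv <- filter(cand, !.data$eliminated)
  if (nrow(surv) == 0L) {
    abort(paste0(
      "all ", nrow(cand), " candidate models violate the anti-overfitting ",
      "constraints (p <= ", floor(n_obs * max_p_fraction),
      "; |adj R^2 - Q^2| <= ", q2_tolerance,
      "); consider more training data or relaxing the constraints ",
      "explicitly"))
  }
  surv <- surv |>
    mutate(name_key = purrr::map_chr(.data$predictors,
                                     ~ paste(sort(.x), collapse = ","))) |>
    arrange(desc(.data$adj_r2), .data$p, .data$name_key)
  winner <- surv$model[[1]]
  attr(winner, "selection") <- select(cand, "set_id", "p", "adj_r2",
                                      "loto_q2", "q2_gap", "eliminated")
  winner
}

#' Fit the full selection pipeline on a design matrix
#'
#' Runs two-round stability selection, refits each candidate with OLS,
#' applies the anti-overfitting constraints, and returns the selected model.
#'
#' @param fm An imputed `trust_matrix`.
#' @param config A [selection_config()].
#' @inheritParams select_model
#' @return The selected `trust_model`; attribute `"candidates"` holds the
#'   candidate table and `"stability"` the selection object.
#' @export
fit_trust_model <- function(fm, config = selection_config(),
                            max_p_fraction = 0.2, q2_tolerance = 0.2) {
  stopifnot(inherits(fm, "trust_matrix"))
  sel <- lasso_stability_select(fm, config = config)
  cand <- evaluate_candidates(fm, sel$round2_sets)
  winner <- select_model(cand, n_obs = nrow(fm$X),
                         max_p_fraction = max_p_fraction,
                         q2_tolerance = q2_tolerance)
  attr(winner, "candidates") <- cand
  attr(winner, "stability") <- sel
  winner
}
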