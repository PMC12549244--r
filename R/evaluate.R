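# External validation harness: leave-one-trial-out-per-session train/test
# splitting, repeated Monte-Carlo cross-validation, test metrics, and the
# all-data descriptive model.

#' Leave-one-trial-out-per-session split scheme
#'
#' For every (participant, session) pair one trial is withheld uniformly at
#' random: its epochs form the test set (1/6 of the data under the default
#' design) and all remaining epochs form the training set.
#'
#' @param design A [study_design()].
#' @param seed Integer seed.
#' @return An object of class `lotops_split`: tibble with `participant`,
#'   `session`, `withheld_trial`.
#' @export
lotops_split <- function(design, seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  assert_that(design$n_trials >= 2L,
              "lotops_split needs at least 2 trials per session")
  grid <- tidyr::expand_grid(participant = seq_len(design$n_participants),
                             session = seq_len(design$n_sessions))
  grid$withheld_trial <- with_seed(child_seed(seed, "lotops"),
                                   sample.int(design$n_trials, nrow(grid),
                                              replace = TRUE))
  class(grid) <- c("lotops_split", class(grid))
  grid
}

# TRUE for epochs that fall in the split's test partition.
is_test_epoch <- function(keys, scheme) {
  k <- paste(keys$participant, keys$session, keys$trial)
  s <- paste(scheme$participant, scheme$session, scheme$withheld_trial)
  k %in% s
}

subset_matrix <- function(fm, sel) {
  fm$X <- fm$X[sel, , drop = FALSE]
  fm$y <- fm$y[sel]
  fm$mask <- fm$mask[sel, , drop = FALSE]
  if (!is.null(fm$imputed)) fm$imputed <- fm$imputed[sel, , drop = FALSE]
  fm$index <- fm$index[sel, , drop = FALSE]
  fm
}

#' Prediction-error metrics
#'
#' Root mean square error, median absolute error (the MAE reported
#' throughout this package is the *median*, not the mean, of absolute
#' errors), and predictive Q^2 with a configurable reference mean (the
#' training-partition mean when scoring held-out data).
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @param y_ref_mean Reference mean for the Q^2 denominator (defaults to
#'   `mean(y_true)`).
#' @return Tibble with `rmse`, `mae`, `q2`, `n`.
#' @export
compute_metrics <- function(y_true, y_pred, y_ref_mean = mean(y_true)) {
  assert_that(length(y_true) == length(y_pred) && length(y_true) >= 1L,
              "y_true and y_pred must be non-empty and equal length")
  err <- y_true - y_pred
  tibble(rmse = sqrt(mean(err^2)),
         mae = median(abs(err)),
         q2 = 1 - sum(err^2) / sum((y_true - y_ref_mean)^2),
         n = length(y_true))
}

#' Run leave-one-trial-out-per-session Monte-Carlo cross-validation
#'
#' Repeats the full pipeline over `n_splits` random train/test splits: per
#' split, the versioned design matrix is rebuilt with participant
#' standardization statistics (versions 7/8) from training epochs only,
#' missing cells are imputed, two-round stability selection and constrained
#' model selection run on the training partition, and the selected model is
#' scored on the withheld trials (predictions capped to `[0, 1]`).
#'
#' @param feats A [extract_features()] result.
#' @param config A [selection_config()].
#' @param n_splits Number of Monte-Carlo splits (default 10).
#' @param seed Integer seed driving the split sequence.
#' @param report_split Split used for the per-participant RMSE table and
#'   stored predictions (default: the last split).
#' @inheritParams select_model
#' @return An object of class `trust_mccv`: list with `splits` (one row per
#'   split: `adj_r2`, `model_q2`, `test_q2`, `rmse`, `mae`, `predictors`,
#'   `capped`), `summary` (mean and SD rows), `per_participant_rmse`,
#'   `predictions` (report split), `schemes`, and `models`.
#' @export
run_mccv <- function(feats, config = selection_config(), n_splits = 10L,
                     seed = 1L, report_split = n_splits,
                     max_p_fraction = 0.2, q2_tolerance = 0.2) {
  stopifnot(inherits(feats, "trust_features"))
  assert_that(n_splits >= 1L, "n_splits must be at least 1")
  rows <- vector("list", n_splits)
  schemes <- vector("list", n_splits)
  models <- vector("list", n_splits)
  predictions <- NULL
  per_part <- NULL
  for (i in seq_len(n_splits)) {
    scheme <- lotops_split(feats$design, seed = child_seed(seed, "split", i))
    schemes[[i]] <- scheme
    test_sel <- is_test_epoch(feats$index, scheme)
    train_keys <- feats$index[!test_sel,
                              c("participant", "session", "trial", "epoch")]
    fm <- build_design_matrix(feats, train_keys = train_keys)
    fm <- impute_missing(fm)
    fm_train <- subset_matrix(fm, !test_sel)
    fm_test <- subset_matrix(fm, test_sel)
    cfg <- config
    cfg$seed <- child_seed(seed, "fit", i)
    model <- fit_trust_model(fm_train, cfg,
                             max_p_fraction = max_p_fraction,
                             q2_tolerance = q2_tolerance)
    models[[i]] <- model
    pred <- predict_trust(model, fm_test)
    m <- compute_metrics(fm_test$y, pred$.pred,
                         y_ref_mean = mean(fm_train$y))
    rows[[i]] <- tibble(split = i, adj_r2 = model$adj_r2,
                        model_q2 = model$loto_q2, test_q2 = m$q2,
                        rmse = m$rmse, mae = m$mae,
                        predictors = model$p, capped = sum(pred$.capped))
    if (i == report_split) {
      predictions <- bind_cols(fm_test$index, pred)
      per_part <- predictions |>
        group_by(.data$participant) |>
        summarise(rmse = sqrt(mean((.data$y - .data$.pred)^2)),
                  .groups = "drop")
    }
  }
  splits <- purrr::list_rbind(rows)
  num <- select(splits, -"split")
  summary <- bind_rows(
    bind_cols(tibble(stat = "mean"), summarise(num, across(everything(), mean))),
    bind_cols(tibble(stat = "sd"), summarise(num, across(everything(), sd)))
  )
  structure(list(splits = splits, summary = summary,
                 per_participant_rmse = per_part,
                 predictions = predictions, schemes = schemes,
                 models = models, report_split = report_split,
                 config = config, seed = seed),
            class = "trust_mccv")
}

#' @export
print.trust_mccv <- function(x, ...) {
  cat("<trust_mccv> ", nrow(x$splits), " splits\n", sep = "")
  print(x$splits)
  cat("mean test Q^2 = ",
      round(x$summary$test_q2[x$summary$stat == "mean"], 3),
      " +- ", round(x$summary$test_q2[x$summary$stat == "sd"], 3),
      "\n", sep = "")
  invisible(x)
}

#' @rdname run_mccv
#' @param x A `trust_mccv`.
#' @param ... Unused.
#' @export
tidy.trust_mccv <- function(x, ...) x$splits

#' @rdname run_mccv
#' @export
glance.trust_mccv <- function(x, ...) {
  m <- x$summary[x$summary$stat == "mean", -1]
  s <- x$summary[x$summary$stat == "sd", -1]
  bind_cols(setNames(m, paste0(names(m), "_mean")),
            setNames(s, paste0(names(s), "_sd")))
}

#' Fit the all-data descriptive model
#'
#' Runs the same selection pipeline on 100% of the epochs (no held-out
#' trials) to describe the dataset: overall adjusted R^2, in-sample RMSE and
#' MAE, and the per-category retention of the selected predictors.
#'
#' @param feats A [extract_features()] result.
#' @param config A [selection_config()].
#' @inheritParams select_model
#' @return An object of class `trust_descriptive`: list with `model`,
#'   `metrics` (adjusted R^2, RMSE, MAE, predictor count), and `retention`
#'   (per feature category: predictors created, retained, percent).
#' @export
fit_descriptive <- function(feats, config = selection_config(),
                            max_p_fraction = 0.2, q2_tolerance = 0.2) {
  stopifnot(inherits(feats, "trust_features"))
  fm <- impute_missing(build_design_matrix(feats))
  model <- fit_trust_model(fm, config,
                           max_p_fraction = max_p_fraction,
                           q2_tolerance = q2_tolerance)
  pred <- predict_trust(model, fm)
  err <- fm$y - pred$.pred
  vc <- versioned_columns(feats$dict)
  created <- count(vc, .data$category, name = "created")
  retained <- vc |>
    filter(.data$column %in% model$predictors) |>
    count(.data$category, name = "retained")
  retention <- left_join(created, retained, by = "category") |>
    mutate(retained = ifelse(is.na(.data$retained), 0L, .data$retained),
           pct_retained = 100 * .data$retained / .data$created)
  structure(list(model = model,
                 metrics = tibble(adj_r2 = model$adj_r2,
                                  rmse = sqrt(mean(err^2)),
                                  mae = median(abs(err)),
                                  predictors = model$p),
                 retention = retention),
            class = "trust_descriptive")
}

#' @export
print.trust_descriptive <- function(x, ...) {
  cat("<trust_descriptive> adj R^2 = ", round(x$metrics$adj_r2, 3),
      ", RMSE = ", round(x$metrics$rmse, 3),
      ", MAE = ", round(x$metrics$mae, 3),
      ", ", x$metrics$predictors, " predictors\n", sep = "")
  print(x$retention)
  invisible(x)
}
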