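# Baseline "versions" and design-matrix assembly.

#' Apply one baseline version to active-period feature values
#'
#' The eight versions map a raw epoch value `a` to a baselined predictor:
#' \describe{
#'   \item{v1}{`a - b_trial` (per-trial pre-trial baseline subtracted)}
#'   \item{v2}{`a - b_mean` (participant's mean pre-trial baseline subtracted)}
#'   \item{v3}{`a - b_preexp` (pre-experimental baseline subtracted)}
#'   \item{v4}{`a / b_trial`}
#'   \item{v5}{`a / b_mean`}
#'   \item{v6}{`a / b_preexp`}
#'   \item{v7}{`(a - mu) / sigma` (participant standardization)}
#'   \item{v8}{`a - mu` (participant mean-centering)}
#' }
#' Zero denominators (versions 4-6) and zero participant SD (version 7)
#' yield `NA`, to be filled by hierarchical imputation.
#'
#' @param active Active-period value(s) `a`.
#' @param pretrial_b Per-trial pre-trial baseline `b_trial`.
#' @param mean_pretrial_b Mean pre-trial baseline `b_mean`.
#' @param preexp_b Pre-experimental baseline `b_preexp`.
#' @param participant_mean,participant_sd Participant statistics `mu`, `sigma`.
#' @param version Integer 1-8.
#' @return Numeric of the same length as `active`.
#' @examples
#' apply_feature_version(10, pretrial_b = 8, version = 1)  # 2
#' apply_feature_version(10, pretrial_b = 8, version = 4)  # 1.25
#' @export
apply_feature_version <- function(active, pretrial_b = NA_real_,
                                  mean_pretrial_b = NA_real_,
                                  preexp_b = NA_real_,
                                  participant_mean = NA_real_,
                                  participant_sd = NA_real_,
                                  version) {
  assert_that(length(version) == 1L && version %in% 1:8,
              "version must be a single integer in 1..8")
  # ratio of a value to an identical baseline is 1 (covers the structural
  # 0/0 of features that are constant by construction); other zero
  # denominators are flagged missing
  div <- function(num, den) {
    out <- ifelse(is.na(den) | den == 0, NA_real_, num / den)
    ifelse(!is.na(num) & !is.na(den) & num == den, 1, out)
  }
  div_plain <- function(num, den) {
    ifelse(is.na(den) | den == 0, NA_real_, num / den)
  }
  switch(version,
         active - pretrial_b,
         active - mean_pretrial_b,
         active - preexp_b,
         div(active, pretrial_b),
         div(active, mean_pretrial_b),
         div(active, preexp_b),
         # a constant participant series is flagged missing, never 0/0 -> 1
         div_plain(active - participant_mean, participant_sd),
         active - participant_mean)
}

#' Assemble the versioned design matrix
#'
#' Expands the base feature table into the full predictor matrix: all eight
#' versions of each psychophysiological feature (ECG, EDA, respiration,
#' eye), version 4 only for EEG, version 1 only for fNIRS, and the raw
#' embedded and background measures — 1,774 predictors for the default
#' dictionary.  Participant statistics for versions 7/8 are computed from
#' `train_keys` epochs only (all epochs when `NULL`) so that test epochs
#' never leak into the standardization.
#'
#' @param feats A [extract_features()] result.
#' @param train_keys Optional tibble of (`participant`, `session`, `trial`,
#'   `epoch`) rows to compute participant statistics from.
#' @return An object of class `trust_matrix`: list with `X` (tibble: keys +
#'   predictors), `y`, `mask` (logical missing matrix, pre-imputation),
#'   `imputed` (provenance level matrix, 0 = observed, filled by
#'   [impute_missing()]), `columns` (predictor metadata), and `index`.
#' @export
build_design_matrix <- function(feats, train_keys = NULL) {
  stopifnot(inherits(feats, "trust_features"))
  dict <- feats$dict
  vc <- versioned_columns(dict)
  keys <- select(feats$features, "participant", "session", "trial", "epoch")
  n <- nrow(keys)
  physio <- physio_feature_names()
  A <- as.matrix(select(feats$features, all_of(physio)))

  # align baseline tables to epochs
  pre <- feats$pretrial
  trial_key <- paste(keys$participant, keys$session, keys$trial)
  Bt <- as.matrix(select(pre, all_of(physio)))[
    match(trial_key, paste(pre$participant, pre$session, pre$trial)), ,
    drop = FALSE]
  prem <- pre |>
    group_by(.data$participant, .data$session) |>
    summarise(across(all_of(physio), ~ mean(.x, na.rm = TRUE)),
              .groups = "drop")
  sess_key <- paste(keys$participant, keys$session)
  Bm <- as.matrix(select(prem, all_of(physio)))[
    match(sess_key, paste(prem$participant, prem$session)), , drop = FALSE]
  pexp <- feats$preexp
  Be <- as.matrix(select(pexp, all_of(physio)))[
    match(sess_key, paste(pexp$participant, pexp$session)), , drop = FALSE]

  # participant statistics over training epochs only
  if (is.null(train_keys)) {
    train_sel <- rep(TRUE, n)
  } else {
    tk <- paste(train_keys$participant, train_keys$session,
                train_keys$trial, train_keys$epoch)
    train_sel <- paste(keys$participant, keys$session, keys$trial,
                       keys$epoch) %in% tk
  }
  At <- A[train_sel, , drop = FALSE]
  gp <- keys$participant[train_sel]
  cnt <- rowsum((!is.na(At)) * 1, gp)
  s1 <- rowsum(ifelse(is.na(At), 0, At), gp)
  s2 <- rowsum(ifelse(is.na(At), 0, At^2), gp)
  mu_p <- s1 / cnt
  var_p <- (s2 - s1^2 / cnt) / pmax(cnt - 1, 1)
  var_p[cnt < 2] <- NA
  sd_p <- sqrt(pmax(var_p, 0))
  prow <- match(keys$participant, as.integer(rownames(mu_p)))
  Mu <- mu_p[prow, , drop = FALSE]
  Sd <- sd_p[prow, , drop = FALSE]
  Sd[Sd == 0] <- NA

  div0 <- function(num, den) {
    out <- num / den
    out[!is.na(den) & den == 0] <- NA
    eq <- !is.na(num) & !is.na(den) & num == den
    out[eq] <- 1
    out
  }
  versions <- list(
    `1` = function() A - Bt, `2` = function() A - Bm,
    `3` = function() A - Be, `4` = function() div0(A, Bt),
    `5` = function() div0(A, Bm), `6` = function() div0(A, Be),
    `7` = function() (A - Mu) / Sd, `8` = function() A - Mu
  )
  need_v <- sort(unique(vc$version[!is.na(vc$version)]))
  Vmats <- lapply(need_v, function(v) versions[[as.character(v)]]())
  names(Vmats) <- as.character(need_v)

  X <- matrix(NA_real_, n, nrow(vc), dimnames = list(NULL, vc$column))
  for (i in seq_len(nrow(vc))) {
    if (is.na(vc$version[i])) {
      X[, i] <- feats$features[[vc$base[i]]]
    } else {
      X[, i] <- Vmats[[as.character(vc$version[i])]][, vc$base[i]]
    }
  }
  mask <- is.na(X)
  structure(
    list(
      X = bind_cols(keys, as_tibble(X)),
      y = feats$index$y,
      mask = mask,
      imputed = NULL,
      columns = vc,
      index = feats$index
    ),
    class = "trust_matrix"
  )
}

#' @export
print.trust_matrix <- function(x, ...) {
  cat("<trust_matrix> ", nrow(x$X), " epochs x ", nrow(x$columns),
      " versioned predictors; ", sum(x$mask), " missing cells",
      if (is.null(x$imputed)) " (not yet imputed)" else " (imputed)",
      "\n", sep = "")
  invisible(x)
}

#' Hierarchically impute missing design-matrix cells
#'
#' Fills each missing cell from the closest available level of the protocol
#' hierarchy: the mean of the same feature over (1) the trial's other
#' epochs, then (2) the session's other observations, then (3) the
#' participant's other sessions.  Observed values are never modified and the
#' operation is idempotent.
#'
#' The within-participant hierarchy can run dry for versioned features that
#' are degenerate for a whole participant (e.g. the participant-standardized
#' version of a series that is constant for that participant).  Such cells
#' fall back to the cross-participant column mean (provenance level 4); a
#' column with no observed value anywhere (structurally unobservable) is
#' filled with the inert constant 0 (also level 4).  A cell that cannot be
#' filled by any of these rules is an error naming the cell.
#'
#' @param fm A [build_design_matrix()] result.
#' @param population_fallback Enable the level-4 cross-participant fallback;
#'   with `FALSE`, a cell with no within-participant donor is an error.
#' @return The `trust_matrix` with `X` completed and `imputed` set to the
#'   per-cell provenance level (0 = observed, 1-3 = hierarchy level used,
#'   4 = cross-participant fallback).
#' @export
impute_missing <- function(fm, population_fallback = TRUE) {
  stopifnot(inherits(fm, "trust_matrix"))
  keys <- select(fm$X, "participant", "session", "trial", "epoch")
  X <- as.matrix(select(fm$X, -(1:4)))
  gt <- paste(keys$participant, keys$session, keys$trial)
  gs <- paste(keys$participant, keys$session)
  gp <- as.character(keys$participant)
  obs <- !is.na(X)
  X0 <- ifelse(obs, X, 0)
  gmean <- function(g) {
    s <- rowsum(X0, g); c <- rowsum(obs * 1, g)
    m <- s / c
    list(m = m, s = s, c = c, lev = rownames(s))
  }
  L1 <- gmean(gt); L2 <- gmean(gs); L3p <- gmean(gp)
  i1 <- match(gt, L1$lev); i2 <- match(gs, L2$lev); i3 <- match(gp, L3p$lev)
  lev <- matrix(0L, nrow(X), ncol(X), dimnames = dimnames(X))
  nas <- which(!obs, arr.ind = TRUE)
  if (nrow(nas)) {
    r <- nas[, 1]; cidx <- nas[, 2]
    m1 <- L1$m[cbind(i1[r], cidx)]
    # session level: other observations in the same session
    m2 <- L2$m[cbind(i2[r], cidx)]
    # other sessions of the participant
    s3 <- L3p$s[cbind(i3[r], cidx)] - L2$s[cbind(i2[r], cidx)]
    c3 <- L3p$c[cbind(i3[r], cidx)] - L2$c[cbind(i2[r], cidx)]
    m3 <- ifelse(c3 > 0, s3 / c3, NaN)
    val <- m1; used <- rep(1L, length(val))
    take2 <- !is.finite(val)
    val[take2] <- m2[take2]; used[take2] <- 2L
    take3 <- !is.finite(val)
    val[take3] <- m3[take3]; used[take3] <- 3L
    if (population_fallback) {
      n_obs_col <- colSums(obs)
      col_mean <- ifelse(n_obs_col > 0, colSums(X0) / n_obs_col, 0)
      take4 <- !is.finite(val)
      val[take4] <- col_mean[cidx[take4]]; used[take4] <- 4L
    }
    bad <- !is.finite(val)
    if (any(bad)) {
      b <- which(bad)[1]
      abort(sprintf(
        "no imputation donor for feature '%s' at participant %d session %d trial %d epoch %d",
        colnames(X)[cidx[b]], keys$participant[r[b]], keys$session[r[b]],
        keys$trial[r[b]], keys$epoch[r[b]]))
    }
    X[nas] <- val
    lev[nas] <- used
  }
  fm$X <- bind_cols(keys, as_tibble(X))
  fm$imputed <- lev
  fm
}
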