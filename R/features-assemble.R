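# Feature-extraction orchestration: materialize each trial's signals,
# preprocess per trial (continuous filtering, per-trial ICA), slice into
# epochs, and extract the physiological feature blocks.  Baseline windows go
# through the identical chain.

physio_feature_names <- function() {
  c(ecg_feature_names(), eda_feature_names(), rsp_feature_names(),
    eeg_feature_names(), fnirs_feature_names(), eye_feature_names())
}

# Preprocess + extract the 641 physiological features for a list of
# equal-length epoch bundles treated as one continuous recording.
process_window_set <- function(bundles, duration_s, fs, run_ica = TRUE) {
  n_ep <- length(bundles)
  # --- ECG: concatenate, filter per recording, detect per epoch slice
  ecg_all <- unlist(lapply(bundles, function(b) b$ecg$signal))
  ecg_f <- filter_ecg(ecg_all, fs$ecg)
  spe <- round(duration_s * fs$ecg)
  # --- EDA
  eda_all <- unlist(lapply(bundles, function(b) b$eda$signal))
  eda_c <- clean_eda(eda_all, fs$eda)
  spe10 <- round(duration_s * 10)
  # --- RSP
  rsp_all <- unlist(lapply(bundles, function(b) b$rsp$signal))
  rsp_f <- filter_resp(rsp_all, fs$rsp)
  spr <- round(duration_s * fs$rsp)
  breaths <- detect_breaths(rsp_f, fs$rsp)
  # --- EEG: concatenate channels, bandpass + ICA once per recording
  eeg_all <- do.call(cbind, lapply(bundles, function(b) b$eeg$signal))
  rownames(eeg_all) <- bundles[[1]]$eeg$channels
  eeg_p <- preprocess_eeg(eeg_all, fs$eeg, run_ica = run_ica)
  spg <- round(duration_s * fs$eeg)
  # --- fNIRS
  hbo_all <- do.call(cbind, lapply(bundles, function(b) b$fnirs$hbo))
  hbr_all <- do.call(cbind, lapply(bundles, function(b) b$fnirs$hbr))
  fnirs_f <- filter_fnirs(hbo_all, hbr_all, fs$fnirs)
  spf <- round(duration_s * fs$fnirs)

  lapply(seq_len(n_ep), function(e) {
    t0 <- (e - 1) * duration_s
    idx <- ((e - 1) * spe + 1):(e * spe)
    pk <- detect_r_peaks(ecg_f[idx], fs$ecg)
    f_ecg <- extract_ecg_features(pk$times, duration_s)
    idx10 <- ((e - 1) * spe10 + 1):(e * spe10)
    seg10 <- eda_c$signal[idx10]
    f_eda <- if (eda_c$flag) na_features(eda_feature_names()) else
      extract_eda_features(seg10, decompose_eda(seg10), duration_s)
    idxr <- ((e - 1) * spr + 1):(e * spr)
    ct <- breaths$cycle_times
    ct <- ct[ct >= t0 & ct < t0 + duration_s] - t0
    f_rsp <- extract_resp_features(rsp_f[idxr], ct, fs$rsp)
    idxg <- ((e - 1) * spg + 1):(e * spg)
    f_eeg <- extract_eeg_features(eeg_p$signal[, idxg, drop = FALSE], fs$eeg)
    idxf <- ((e - 1) * spf + 1):(e * spf)
    f_fnirs <- extract_fnirs_features(
      list(hbo = fnirs_f$hbo[, idxf, drop = FALSE],
           hbr = fnirs_f$hbr[, idxf, drop = FALSE]), fs$fnirs)
    f_eye <- extract_eye_features(bundles[[e]]$eye, duration_s)
    c(f_ecg, f_eda, f_rsp, f_eeg, f_fnirs, f_eye)
  })
}

apply_missing_flags <- function(feat_vec, flags) {
  for (s in stream_names()) {
    if (isTRUE(flags[[paste0("miss_", s)]])) {
      pref <- if (s == "eye") "eye_" else paste0(s, "_")
      feat_vec[startsWith(names(feat_vec), pref)] <- NA_real_
    }
  }
  feat_vec
}

#' Extract the full per-epoch feature set of a study
#'
#' Streams every trial through the preprocessing chain (per-trial continuous
#' filtering, per-trial ICA, epoch slicing) and extracts the 641
#' physiological features per epoch; joins the 16 embedded measures and the
#' 25 participant background variables; computes the same physiological
#' features on every pre-trial and pre-experimental baseline window for
#' later versioning.  Stream-epochs flagged missing yield NA features.
#'
#' @param study A [generate_study()] result.
#' @param run_ica Set `FALSE` to skip EEG ICA (faster, artifact power
#'   retained).
#' @param verbose Print per-session progress.
#' @return An object of class `trust_features`: list with `features` (tibble:
#'   keys + 682 base features), `pretrial` and `preexp` baseline feature
#'   tables, `index` (keys, condition, `y`), `design`, and `dict`.
#' @export
extract_features <- function(study, run_ica = TRUE, verbose = FALSE) {
  stopifnot(inherits(study, "trust_study"))
  d <- study$design
  fs <- d$fs
  idx <- study$index
  sessions <- distinct(idx, .data$participant, .data$session)
  feat_rows <- vector("list", nrow(idx))
  pre_rows <- list()
  pexp_rows <- list()
  row_of <- function(p, s, t, e) {
    which(idx$participant == p & idx$session == s &
            idx$trial == t & idx$epoch == e)
  }
  for (si in seq_len(nrow(sessions))) {
    p <- sessions$participant[si]; s <- sessions$session[si]
    if (verbose) message("participant ", p, " session ", s)
    pexp <- baseline_signals(study, p, s, trial = NULL)
    pexp_feats <- process_window_set(list(pexp), d$preexp_baseline_s, fs)[[1]]
    pexp_rows[[length(pexp_rows) + 1L]] <-
      bind_cols(tibble(participant = p, session = s),
                as_tibble_row(as.list(pexp_feats)))
    for (t in seq_len(d$n_trials)) {
      bl <- baseline_signals(study, p, s, trial = t)
      bl_feats <- process_window_set(list(bl), d$pretrial_baseline_s, fs)[[1]]
      pre_rows[[length(pre_rows) + 1L]] <-
        bind_cols(tibble(participant = p, session = s, trial = t),
                  as_tibble_row(as.list(bl_feats)))
      bundles <- lapply(seq_len(d$n_epochs), function(e)
        epoch_signals(study, p, s, t, e))
      ep_feats <- process_window_set(bundles, d$epoch_s, fs)
      for (e in seq_len(d$n_epochs)) {
        ri <- row_of(p, s, t, e)
        fv <- apply_missing_flags(ep_feats[[e]], idx[ri, ])
        feat_rows[[ri]] <- as_tibble_row(as.list(fv))
      }
    }
  }
  physio <- purrr::list_rbind(feat_rows)
  emb <- study$embedded |>
    select("participant", "session", "trial", "epoch",
           all_of(embedded_feature_names()))
  bg <- study$background |>
    select("participant", all_of(background_feature_names()))
  features <- bind_cols(
    select(idx, "participant", "session", "trial", "epoch"), physio) |>
    left_join(emb, by = c("participant", "session", "trial", "epoch")) |>
    left_join(bg, by = "participant")
  structure(
    list(
      features = features,
      pretrial = purrr::list_rbind(pre_rows),
      preexp = purrr::list_rbind(pexp_rows),
      index = select(idx, "participant", "session", "trial", "epoch",
                     "condition", "reliability", "explainability", "y"),
      design = d,
      dict = feature_dictionary()
    ),
    class = "trust_features"
  )
}

#' @export
print.trust_features <- function(x, ...) {
  cat("<trust_features> ", nrow(x$features), " epochs x ",
      ncol(x$features) - 4L, " base features (",
      sum(is.na(as.matrix(select(x$features, -(1:4))))),
      " missing cells)\n", sep = "")
  invisible(x)
}
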