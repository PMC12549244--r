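# The frozen feature dictionary.  Category totals (ECG 28, EDA 63, RSP 28,
# EEG 125, fNIRS 360, eye 37, embedded 16, background 25) are structural
# constants of the pipeline; tests assert them at load.

.eeg_channels <- c(
  "fp1", "fp2", "f7", "f3", "fz", "f4", "f8",
  "t7", "c3", "cz", "c4", "t8",
  "p7", "p3", "pz", "p4", "p8",
  "o1", "o2"
)

.eeg_bands <- c("delta", "theta", "alpha", "beta", "gamma")

# Band edges in Hz.  Gamma is nominally 30-80 Hz but the EEG chain lowpasses
# at 55 Hz, so gamma power is integrated over 30-55 Hz.
.eeg_band_edges <- list(
  delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
  beta = c(13, 30), gamma = c(30, 55)
)

# 10-20 regional groupings used for the region-mean EEG features.
.eeg_regions <- list(
  prefrontal = c("fp1", "fp2", "f3", "fz", "f4", "f7", "f8"),
  central    = c("c3", "cz", "c4"),
  parietal   = c("p3", "pz", "p4"),
  occipital  = c("o1", "o2"),
  temporal   = c("t7", "t8", "p7", "p8"),
  whole      = .eeg_channels
)

.stat9 <- c("mean", "sd", "min", "max", "range", "slope", "auc", "skew", "kurtosis")

ecg_feature_names <- function() {
  paste0("ecg_", c(
    "rr_mean", "rr_median", "sdnn", "rmssd", "sdsd", "pnn50", "pnn20",
    "rr_min", "rr_max", "rr_range", "rr_cv",
    "hr_mean", "hr_min", "hr_max", "rr_skew", "rr_kurtosis",
    "vlf_power", "lf_power", "hf_power", "total_power",
    "lf_hf_ratio", "lf_nu", "hf_nu", "lf_peak_freq", "hf_peak_freq",
    "sd1", "sd2", "sd1_sd2_ratio"
  ))
}

eda_feature_names <- function() {
  series <- c("scl", "tonic", "phasic", "driver", "deriv")
  stat_part <- as.vector(t(outer(series, .stat9, function(a, b) paste0("eda_", a, "_", b))))
  scr_part <- paste0("eda_", c(
    "scr_count", "scr_rate",
    "scr_amp_mean", "scr_amp_sd", "scr_amp_max", "scr_amp_min", "scr_amp_sum",
    "scr_rise_mean", "scr_rise_sd", "scr_rise_max",
    "scr_rec_mean", "scr_rec_sd", "scr_rec_max",
    "scr_first_latency", "iscr", "scr_isi_mean", "scr_isi_sd",
    "scr_time_fraction"
  ))
  c(stat_part, scr_part)
}

rsp_feature_names <- function() {
  paste0("rsp_", c(
    "bi_mean", "bi_sd", "bi_min", "bi_max", "bi_range", "bi_cv",
    "bi_skew", "bi_kurtosis", "breath_rate",
    "amp_mean", "amp_sd", "amp_min", "amp_max", "amp_range", "amp_cv",
    "inhale_mean", "inhale_sd", "exhale_mean", "exhale_sd", "ie_ratio",
    "sig_mean", "sig_sd", "sig_skew", "sig_kurtosis", "sig_rms",
    "sig_slope", "sig_auc",
    "dom_freq"
  ))
}

eeg_feature_names <- function() {
  chan <- as.vector(t(outer(.eeg_channels, .eeg_bands, function(a, b) paste0("eeg_", a, "_", b))))
  regn <- as.vector(t(outer(names(.eeg_regions), .eeg_bands, function(a, b) paste0("eeg_", a, "_", b))))
  c(chan, regn)
}

fnirs_feature_names <- function(n_channels = 20L) {
  hbo <- c("max", "ttmax", "mean", "var", "skew", "kurtosis", "rms", "slope", "auc")
  hbr <- c("min", "ttmin", "mean", "var", "skew", "kurtosis", "rms", "slope", "auc")
  unlist(lapply(seq_len(n_channels), function(ch) {
    tag <- sprintf("fnirs_ch%02d", ch)
    c(paste0(tag, "_hbo_", hbo), paste0(tag, "_hbr_", hbr))
  }))
}

eye_feature_names <- function() {
  paste0("eye_", c(
    "pupil_mean", "pupil_sd", "pupil_min", "pupil_max", "pupil_range",
    "pupil_slope", "pupil_skew", "pupil_kurtosis", "pupil_rms",
    "pcv", "pdv", "vel_mean_abs",
    "blink_count", "blink_rate", "blink_dur_mean", "blink_dur_sd",
    "blink_dur_min", "blink_dur_max", "ibi_mean", "ibi_sd", "closure_frac",
    paste0("dwell_aoi", 1:4), paste0("fixcount_aoi", 1:4),
    "fix_dur_mean", "fix_dur_sd", "fix_count",
    "sacc_count", "sacc_rate", "sacc_amp_mean",
    "aoi_transitions", "aoi_entropy"
  ))
}

embedded_feature_names <- function() {
  paste0("emb_", c(
    "session", "trial", "epoch",
    "review_time_total", "review_time_avg",
    "pct_reviewed", "pct_ignored",
    "pct_agreement", "pct_passive_agreement",
    "decision_latency", "pct_rereviewed",
    "map_selections", "pct_map_interactions",
    "reliance_slider", "screen_switches", "explainability"
  ))
}

background_feature_names <- function() {
  paste0("bg_", c(
    "big5_extraversion", "big5_agreeableness", "pas_high_expectations",
    "cvs_masculinity", "propensity_to_trust", "aicp",
    "utaut_performance", "utaut_effort",
    "age", "sex", "race", "ethnicity", "dominant_hand",
    "videogame_exp", "robotics_exp", "navaid_use",
    "aerospace_display_exp", "military_monitoring_exp",
    "sleep_hours",
    "pvt_rt_mean", "pvt_rt_median", "pvt_rt_sd", "pvt_lapses",
    "pvt_false_starts", "pvt_rt_fastest10"
  ))
}

#' The feature dictionary
#'
#' Enumerates every base (unversioned) feature the pipeline extracts, its
#' sensor category, and which baseline "versions" apply to it.  The
#' psychophysiological categories (ECG, EDA, respiration, eye) receive all
#' eight versions; EEG receives only version 4 (ratio to the per-trial
#' pre-trial baseline), fNIRS only version 1 (difference from the per-trial
#' pre-trial baseline); embedded and background measures are not baselined.
#'
#' @return A tibble with columns `name`, `category`, and `versions`
#'   (list-column of integer version ids, `integer(0)` for unversioned
#'   features).  Category totals are ECG 28, EDA 63, respiration 28, EEG 125,
#'   fNIRS 360, eye 37, embedded 16, background 25 (682 base features;
#'   1,774 versioned predictors).
#' @examples
#' dict <- feature_dictionary()
#' dplyr::count(dict, category)
#' @export
feature_dictionary <- function() {
  blocks <- list(
    ecg = ecg_feature_names(),
    eda = eda_feature_names(),
    rsp = rsp_feature_names(),
    eeg = eeg_feature_names(),
    fnirs = fnirs_feature_names(),
    eye = eye_feature_names(),
    embedded = embedded_feature_names(),
    background = background_feature_names()
  )
  versions <- list(
    ecg = 1:8, eda = 1:8, rsp = 1:8, eye = 1:8,
    eeg = 4L, fnirs = 1L, embedded = integer(0), background = integer(0)
  )
  out <- purrr::imap(blocks, function(nms, cat) {
    tibble(
      name = nms, category = cat,
      versions = rep(list(as.integer(versions[[cat]])), length(nms))
    )
  })
  purrr::list_rbind(out)
}

# Expected per-category base feature counts (structural constants).
dictionary_counts <- function() {
  c(ecg = 28L, eda = 63L, rsp = 28L, eeg = 125L, fnirs = 360L,
    eye = 37L, embedded = 16L, background = 25L)
}

#' Versioned predictor names
#'
#' Expands the base dictionary into the full predictor list: one column per
#' applicable version of each psychophysiological/EEG/fNIRS feature
#' (suffix `_v1` ... `_v8`) plus the unversioned embedded and background
#' measures.
#'
#' @param dict A dictionary from [feature_dictionary()].
#' @return A tibble with columns `column` (predictor name), `base` (base
#'   feature name), `category`, `version` (integer, `NA` for unversioned).
#' @export
versioned_columns <- function(dict = feature_dictionary()) {
  rows <- purrr::pmap(dict, function(name, category, versions) {
    if (length(versions) == 0L) {
      tibble(column = name, base = name, category = category,
             version = NA_integer_)
    } else {
      tibble(column = paste0(name, "_v", versions), base = name,
             category = category, version = versions)
    }
  })
  purrr::list_rbind(rows)
}
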