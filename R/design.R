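# Study design and planted-trust configuration.

#' Study design
#'
#' Describes the protocol hierarchy and timing of the emulated
#' human-autonomy-teaming study: participants complete several sessions (one
#' autonomous-system condition per session), each session holds a number of
#' trials, and each trial is divided into fixed-length epochs ending in a
#' trust slider report.  A 2-minute pre-experimental rest baseline precedes
#' the first trial of every session and a 45-s pre-trial baseline precedes
#' trials 2 onward (trial 1 reuses the tail of the pre-experimental
#' baseline).
#'
#' Defaults reproduce the reference protocol: 12 participants x 4 sessions x
#' 6 trials x 8 epochs of 45 s (2,304 epochs), with the four sessions
#' carrying the four reliability (67% / 84%) x explainability (low / high)
#' combinations in a per-participant randomized order.
#'
#' @param n_participants,n_sessions,n_trials,n_epochs Protocol counts.
#' @param epoch_s Epoch duration in seconds.
#' @param pretrial_baseline_s Pre-trial baseline duration in seconds.
#' @param preexp_baseline_s Pre-experimental baseline duration in seconds.
#' @param fs Named list of sampling rates in Hz per stream
#'   (`ecg`, `eda`, `rsp`, `eeg`, `fnirs`, `pupil`).
#' @return An object of class `study_design`.
#' @examples
#' d <- study_design()
#' d$n_participants * d$n_sessions * d$n_trials * d$n_epochs
#' @export
study_design <- function(n_participants = 12L, n_sessions = 4L,
                         n_trials = 6L, n_epochs = 8L,
                         epoch_s = 45, pretrial_baseline_s = 45,
                         preexp_baseline_s = 120,
                         fs = list(ecg = 500, eda = 32, rsp = 32,
                                   eeg = 250, fnirs = 10, pupil = 120)) {
  counts <- c(n_participants, n_sessions, n_trials, n_epochs)
  assert_that(all(counts >= 1) && all(counts == as.integer(counts)),
              "all design counts must be positive integers")
  assert_that(epoch_s > 0 && pretrial_baseline_s > 0 && preexp_baseline_s > 0,
              "all durations must be positive")
  assert_that(all(unlist(fs) > 0), "all sampling rates must be positive")
  needed <- c("ecg", "eda", "rsp", "eeg", "fnirs", "pupil")
  assert_that(all(needed %in% names(fs)),
              paste("fs must name rates for:", paste(needed, collapse = ", ")))
  structure(
    list(
      n_participants = as.integer(n_participants),
      n_sessions = as.integer(n_sessions),
      n_trials = as.integer(n_trials),
      n_epochs = as.integer(n_epochs),
      epoch_s = epoch_s,
      pretrial_baseline_s = pretrial_baseline_s,
      preexp_baseline_s = preexp_baseline_s,
      fs = fs
    ),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design> ", x$n_participants, " participants x ", x$n_sessions,
      " sessions x ", x$n_trials, " trials x ", x$n_epochs, " epochs of ",
      x$epoch_s, " s\n", sep = "")
  cat("  baselines: pre-experimental ", x$preexp_baseline_s,
      " s, pre-trial ", x$pretrial_baseline_s, " s\n", sep = "")
  invisible(x)
}

n_epochs_total <- function(design) {
  design$n_participants * design$n_sessions * design$n_trials * design$n_epochs
}

# The session condition grid: four autonomous-system conditions crossing
# reliability 67%/84% with explainability low/high.
condition_grid <- function() {
  tibble(
    condition = 1:4,
    reliability = c(0.67, 0.67, 0.84, 0.84),
    explainability = c("low", "high", "low", "high")
  )
}

# Features the generator can plant trust structure on, with the generator
# parameter each one modulates.  Each link is monotone in the latent z-score;
# the feature extractors recover the parameter (noisily) from the raw signal.
plantable_features <- function() {
  c(
    "ecg_rr_mean", "ecg_sdnn",
    "eda_scl_mean", "eda_scl_slope", "eda_scr_amp_mean",
    "rsp_breath_rate", "rsp_amp_mean",
    "eeg_pz_alpha", "eeg_fz_theta", "eeg_o1_alpha",
    "fnirs_ch01_hbo_max", "fnirs_ch05_hbo_max",
    "eye_pupil_mean", "eye_blink_rate", "eye_fix_dur_mean"
  )
}

#' Base features that read out each plantable latent
#'
#' A planted latent modulates a generator parameter, and every feature that
#' summarizes the affected signal property carries its signal: a heart-rate
#' shift moves all R-R level statistics, not only the mean; an SCR-amplitude
#' shift moves the phasic component's summary statistics; an fNIRS response
#' amplitude moves HbO and (mirrored) HbR summaries on that channel.
#' Support-recovery checks therefore count a planted latent as recovered
#' when the selected model retains *any* version of *any* feature in its
#' trace set — name-exact matching would miss a model that captured the
#' latent through an equally valid sibling readout.
#'
#' @return Named list: for each [plantable_features()] entry, the character
#'   vector of base feature names that are direct readouts of that latent.
#' @export
planted_trace_features <- function() {
  ecg_level <- paste0("ecg_", c("rr_mean", "rr_median", "rr_min", "rr_max",
                                "hr_mean", "hr_min", "hr_max"))
  ecg_var <- paste0("ecg_", c("sdnn", "rmssd", "sdsd", "pnn50", "pnn20",
                              "rr_range", "rr_cv", "rr_min", "rr_max",
                              "hr_min", "hr_max", "sd1", "sd2",
                              "sd1_sd2_ratio", "vlf_power", "lf_power",
                              "hf_power", "total_power"))
  scl_level <- paste0("eda_", c("scl_mean", "scl_min", "scl_max", "scl_auc",
                                "tonic_mean", "tonic_min", "tonic_max",
                                "tonic_auc"))
  scl_slope <- paste0("eda_", c("scl_slope", "tonic_slope", "deriv_mean",
                                "scl_range", "tonic_range"))
  scr_amp <- paste0("eda_", c("scr_amp_mean", "scr_amp_max", "scr_amp_min",
                              "scr_amp_sum", "iscr", "phasic_mean",
                              "phasic_max", "phasic_sd", "phasic_auc",
                              "driver_mean", "driver_max", "driver_sd",
                              "driver_auc", "scr_time_fraction"))
  rsp_rate <- paste0("rsp_", c("breath_rate", "bi_mean", "bi_min", "bi_max",
                               "dom_freq", "inhale_mean", "exhale_mean"))
  rsp_amp <- paste0("rsp_", c("amp_mean", "amp_min", "amp_max", "amp_range",
                              "sig_sd", "sig_rms", "sig_auc"))
  fnirs_tr <- function(ch) {
    tag <- sprintf("fnirs_ch%02d", ch)
    c(paste0(tag, "_hbo_", c("max", "mean", "var", "rms", "auc")),
      paste0(tag, "_hbr_", c("min", "mean", "var", "rms", "auc")))
  }
  list(
    ecg_rr_mean = ecg_level,
    ecg_sdnn = ecg_var,
    eda_scl_mean = scl_level,
    eda_scl_slope = scl_slope,
    eda_scr_amp_mean = scr_amp,
    rsp_breath_rate = rsp_rate,
    rsp_amp_mean = rsp_amp,
    eeg_pz_alpha = c("eeg_pz_alpha", "eeg_parietal_alpha", "eeg_whole_alpha"),
    eeg_fz_theta = c("eeg_fz_theta", "eeg_prefrontal_theta",
                     "eeg_whole_theta"),
    eeg_o1_alpha = c("eeg_o1_alpha", "eeg_occipital_alpha",
                     "eeg_whole_alpha"),
    fnirs_ch01_hbo_max = fnirs_tr(1),
    fnirs_ch05_hbo_max = fnirs_tr(5),
    eye_pupil_mean = paste0("eye_pupil_", c("mean", "min", "max", "rms")),
    eye_blink_rate = paste0("eye_", c("blink_count", "blink_rate",
                                      "ibi_mean", "closure_frac")),
    eye_fix_dur_mean = paste0("eye_", c("fix_dur_mean", "fix_dur_sd",
                                        "fix_count", "sacc_count",
                                        "sacc_rate",
                                        paste0("fixcount_aoi", 1:4)))
  )
}

#' Fraction of planted latents covered by a model's support
#'
#' @param model A `trust_model`.
#' @param active_features The study's planted feature names.
#' @return Fraction in `[0, 1]` of planted latents with at least one trace
#'   feature (any version) in the model's predictors.
#' @export
planted_support_recovery <- function(model, active_features) {
  vc <- versioned_columns()
  bases <- unique(vc$base[vc$column %in% model$predictors])
  traces <- planted_trace_features()
  hits <- vapply(active_features, function(f) {
    any(traces[[f]] %in% bases)
  }, logical(1))
  mean(hits)
}

#' Planted trust ground truth specification
#'
#' Configures the sparse linear structure the generator plants between latent
#' physiological states and the trust report: per epoch, latent standard
#' normal scores `z` drive a subset of generator parameters (heart rate, skin
#' conductance level, breathing rate, EEG band power, fNIRS response
#' amplitude, pupil size, ...), and trust is
#' `clip(intercept + condition shift + participant shift + sum(beta * z) + noise, 0, 1)`.
#'
#' The planted latents share a common arousal factor
#' (`latent_correlation`): physiological streams co-vary, and with
#' equicorrelated latents and equal same-sign coefficients every planted
#' feature carries a marginal standardized effect of
#' `sqrt(target_r2 / k) * sqrt(1 + (k - 1) * latent_correlation)` SD of the
#' trust signal — well above 0.3 SD at the defaults — while the joint
#' planted term still explains `target_r2` of the pre-clipping variance.
#' `noise_sd` is derived from `target_r2` accordingly.
#'
#' @param active_features Character vector of planted base feature names;
#'   must be a subset of [plantable_features()].
#' @param coefficients Numeric vector of trust-units-per-SD effects, one per
#'   active feature.  Default: equal positive magnitudes scaled so the
#'   planted linear term has SD `signal_sd` under `latent_correlation`
#'   (each link's physiological direction is set by the generator's
#'   latent-to-parameter maps).
#' @param latent_correlation Pairwise correlation of the planted latents
#'   (common arousal factor share), in `[0, 1)`.
#' @param intercept Mean trust level.
#' @param noise_sd Epoch-level trust noise SD; if `NULL`, derived from
#'   `target_r2`.
#' @param target_r2 Signal fraction of pre-clipping trust variance.
#' @param signal_sd SD of the planted linear term on the trust scale.
#' @param condition_effects Named numeric: additive trust shifts
#'   `reliability_high` and `explainability_high` applied at session level.
#' @param participant_sd SD of the participant-level trust intercept shift;
#'   a fraction `dispositional_weight` of that shift is carried by the
#'   participant's propensity-to-trust background score.
#' @param dispositional_weight See `participant_sd`.
#' @return An object of class `trust_spec`.
#' @export
trust_spec <- function(active_features = plantable_features(),
                       coefficients = NULL,
                       intercept = 0.55,
                       noise_sd = NULL,
                       target_r2 = 0.85,
                       signal_sd = 0.17,
                       latent_correlation = 0.25,
                       condition_effects = c(reliability_high = 0.05,
                                             explainability_high = 0.03),
                       participant_sd = 0.06,
                       dispositional_weight = 0.6) {
  bad <- setdiff(active_features, plantable_features())
  assert_that(length(bad) == 0L,
              paste("unknown planted feature(s):", paste(bad, collapse = ", ")))
  assert_that(latent_correlation >= 0 && latent_correlation < 1,
              "latent_correlation must be in [0, 1)")
  k <- length(active_features)
  rho <- latent_correlation
  if (is.null(coefficients)) {
    # Var(sum beta z) = mag^2 * k * (1 + (k - 1) rho) for equal betas
    mag <- signal_sd / sqrt(k * (1 + (k - 1) * rho))
    coefficients <- rep(mag, k)
  }
  assert_that(length(coefficients) == k,
              "coefficients must match active_features in length")
  if (is.null(noise_sd)) {
    assert_that(target_r2 > 0 && target_r2 < 1, "target_r2 must be in (0, 1)")
    b <- as.numeric(coefficients)
    sig_var <- sum(b^2) + rho * (sum(b)^2 - sum(b^2))
    noise_sd <- sqrt(sig_var * (1 - target_r2) / target_r2)
  }
  assert_that(noise_sd >= 0, "noise_sd must be non-negative")
  structure(
    list(
      active_features = active_features,
      coefficients = setNames(as.numeric(coefficients), active_features),
      intercept = intercept,
      noise_sd = noise_sd,
      latent_correlation = rho,
      condition_effects = condition_effects,
      participant_sd = participant_sd,
      dispositional_weight = dispositional_weight
    ),
    class = "trust_spec"
  )
}

#' @export
print.trust_spec <- function(x, ...) {
  cat("<trust_spec> ", length(x$active_features),
      " planted features, intercept ", x$intercept,
      ", noise_sd ", signif(x$noise_sd, 3), "\n", sep = "")
  invisible(x)
}
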