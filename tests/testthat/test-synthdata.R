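test_that("study generation honours the protocol hierarchy", {
  # default protocol: 12 x 4 x 6 x 8
  study <- generate_study(seed = 1)
  expect_equal(nrow(study$index), 2304L)
  expect_true(all(study$index$y >= 0 & study$index$y <= 1))
  # four conditions per participant, each session distinct
  conds <- study$index |>
    dplyr::distinct(participant, session, reliability, explainability)
  expect_equal(nrow(conds), 48L)
  percond <- dplyr::count(conds, participant)
  expect_true(all(percond$n == 4L))

  tiny <- generate_study(study_design(n_participants = 1, n_sessions = 1,
                                      n_trials = 1, n_epochs = 8), seed = 2)
  expect_equal(nrow(tiny$index), 8L)
})

test_that("identical seeds reproduce the dataset field by field", {
  d <- study_design(n_participants = 1, n_sessions = 2, n_trials = 2,
                    n_epochs = 3, fs = reduced_rates())
  a <- generate_study(d, seed = 5)
  b <- generate_study(d, seed = 5)
  expect_identical(a$index, b$index)
  expect_identical(a$embedded, b$embedded)
  expect_identical(a$truth$z, b$truth$z)
  sa <- epoch_signals(a, 1, 1, 2, 1)
  sb <- epoch_signals(b, 1, 1, 2, 1)
  expect_identical(sa$ecg$signal, sb$ecg$signal)
  expect_identical(sa$eeg$signal, sb$eeg$signal)
  expect_identical(sa$eda$signal, sb$eda$signal)
  c_ <- generate_study(d, seed = 6)
  expect_false(identical(a$index$y, c_$index$y))
})

test_that("ECG generator places beats at the requested rate and variability", {
  e <- generate_ecg(45, mean_hr_bpm = 60, hrv_sd_ms = 0, fs = 500, seed = 3)
  expect_true(abs(length(e$r_times) - 45) <= 1)
  expect_lt(sd(e$rr_s), 1e-12)  # uniform R-R
  # stated R-R variability reproduced at n >= 200 beats
  e2 <- generate_ecg(250, mean_hr_bpm = 72, hrv_sd_ms = 50, fs = 250, seed = 4)
  expect_gt(length(e2$rr_s), 200)
  expect_lt(abs(sd(e2$rr_s) * 1000 - 50) / 50, 0.2)
  # 60 Hz contaminant present in the raw spectrum
  w <- trustdyn:::welch_psd(e$signal, 500, 2048)
  p60 <- trustdyn:::band_power(w, 59.5, 60.5)
  pref <- trustdyn:::band_power(w, 45, 55) / 10
  expect_gt(p60, 5 * pref)
  expect_error(generate_ecg(45, mean_hr_bpm = 20), "30-200")
  expect_error(generate_ecg(0.4, mean_hr_bpm = 60), "one beat")
})

test_that("EDA generator plants Bateman-shaped responses on a tonic floor", {
  ed <- generate_eda(45, scr_rate_per_min = 0, noise_sd = 0, seed = 2)
  expect_identical(ed$signal, ed$tonic)
  # a single planted response peaks at the drawn amplitude
  found <- FALSE
  for (s in 1:20) {
    ed1 <- generate_eda(45, scr_rate_per_min = 2, scr_amp_uS = 0.5,
                        noise_sd = 0, seed = s)
    if (nrow(ed1$scr_events) == 1L) {
      peak <- max(ed1$signal - ed1$tonic)
      expect_lt(abs(peak - ed1$scr_events$amplitude) /
                  ed1$scr_events$amplitude, 0.1)
      found <- TRUE
      break
    }
  }
  expect_true(found)
  expect_error(generate_eda(45, tonic_level_uS = 0.5), "1-40")
  expect_error(generate_eda(45, scr_rate_per_min = -1), "non-negative")
})

test_that("SCR event counts follow the configured Poisson process", {
  counts <- vapply(1:500, function(s) {
    nrow(generate_eda(45, scr_rate_per_min = 4, fs = 4, seed = s)$scr_events)
  }, numeric(1))
  lam <- 3  # 4/min * 0.75 min
  breaks <- c(-0.5, 0.5, 1.5, 2.5, 3.5, 4.5, 5.5, Inf)
  obs <- table(cut(counts, breaks))
  p <- diff(c(0, ppois(0:5, lam), 1))
  chi <- sum((as.numeric(obs) - 500 * p)^2 / (500 * p))
  expect_lt(chi, qchisq(0.99, df = length(p) - 1))
})

test_that("EEG generator respects band structure, montage, and blink controls", {
  g <- generate_eeg(45, fs = 250, seed = 2)
  expect_equal(dim(g$signal), c(19L, 11250L))
  expect_equal(g$channels, trustdyn:::.eeg_channels)
  targets <- c(delta = 2, theta = 2, alpha = 20, beta = 2, gamma = 2)
  g2 <- generate_eeg(45, fs = 250, seed = 3, band_power_targets = targets,
                     blink_rate_per_min = 0)
  expect_length(g2$blink_times, 0)
  for (ci in 1:19) {
    w <- trustdyn:::welch_psd(g2$signal[ci, ], 250, 500)
    bp <- vapply(trustdyn:::.eeg_band_edges, function(e)
      trustdyn:::band_power(w, e[1], e[2]), numeric(1))
    expect_equal(names(which.max(bp)), "alpha")
  }
  expect_error(generate_eeg(10, n_channels = 12), "allow_nonstandard")
  expect_error(generate_eeg(10, band_power_targets = c(alpha = 1)),
               "canonical bands")
})

test_that("fNIRS generator returns truth parameters with HRF physics", {
  f <- generate_fnirs(45, seed = 2, hrf_peak_s = 6)
  expect_equal(dim(f$hbo), c(20L, 450L))
  expect_equal(f$params$hrf_peak_s, 6)
  k <- trustdyn:::hrf_kernel(10, peak_s = 6)
  expect_lt(abs((which.max(k) - 1) / 10 - 6), 0.2)
  expect_error(generate_fnirs(45, hrf_amp = -1), "non-negative")
})

test_that("respiration generator produces the requested breath cycles", {
  r <- generate_resp(45, breath_rate_bpm = 15, cycle_cv = 0, seed = 2)
  expect_true(length(r$cycle_times) %in% 11:12)
  expect_error(generate_resp(45, breath_rate_bpm = 1), "3-180")
})

test_that("embedded links are monotone in trust with a reliance broadcast", {
  hi <- generate_embedded(rep(1, 4), 1, 1, "high", seed = 1, link_noise = 0)
  lo <- generate_embedded(rep(0, 4), 1, 1, "high", seed = 1, link_noise = 0)
  expect_equal(ncol(hi), 16L)
  expect_named(hi, embedded_feature_names())
  # trusting operators: maximal passive agreement under the noise-free link
  expect_true(all(hi$emb_pct_passive_agreement == 90))
  expect_true(all(hi$emb_pct_passive_agreement >
                    lo$emb_pct_passive_agreement))
  expect_true(all(hi$emb_pct_reviewed <= lo$emb_pct_reviewed))
  expect_true(all(hi$emb_decision_latency < lo$emb_decision_latency))
  expect_equal(unique(hi$emb_reliance_slider),
               hi$emb_reliance_slider[1])  # post-trial broadcast
})

test_that("background generator yields 25 plausible per-participant values", {
  bg <- generate_background(12, seed = 1)
  expect_equal(dim(bg$background), c(12L, 26L))
  expect_named(bg$background, c("participant", background_feature_names()))
  expect_true(all(bg$background$bg_propensity_to_trust >= 1 &
                    bg$background$bg_propensity_to_trust <= 7))
  expect_length(bg$propensity_z, 12)
})

test_that("missingness injection respects flags, targets, and structure", {
  study <- small_study()
  same <- inject_missingness(study, epoch_drop_p = 0, trial_drop_p = 0,
                             session_stream_drop_count = 0)
  expect_identical(same$index, study$index)

  # default probabilities land near the configured imputed-data target
  big <- generate_study(seed = 31)
  miss <- inject_missingness(big, seed = 32)
  flags <- as.matrix(dplyr::select(miss$index, dplyr::starts_with("miss_")))
  frac <- mean(flags)
  target <- 1 - (1 - 0.002) * (1 - 0.0004)
  expect_lt(abs(frac - target), 0.0015)
  # trust reports are never dropped
  expect_true(all(is.finite(miss$index$y)))

  # a whole-session stream drop flags every epoch of that session
  one <- inject_missingness(study, epoch_drop_p = 0, trial_drop_p = 0,
                            session_stream_drop_count = 1, seed = 7)
  flags1 <- dplyr::select(one$index, participant, session,
                          dplyr::starts_with("miss_")) |>
    tidyr::pivot_longer(dplyr::starts_with("miss_"),
                        names_to = "stream", values_to = "miss") |>
    dplyr::filter(miss)
  expect_gt(nrow(flags1), 0)
  hit <- dplyr::distinct(flags1, participant, session, stream)
  expect_equal(nrow(hit), 1L)
  n_flagged <- nrow(flags1)
  expect_equal(n_flagged,
               study$design$n_trials * study$design$n_epochs)

  expect_error(
    inject_missingness(study, epoch_drop_p = 1, trial_drop_p = 0),
    "entire participant-session")
})
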