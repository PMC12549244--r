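test_that("ECG features: counts, uniform-beat case, and RMSSD hand value", {
  uni <- extract_ecg_features(seq(0.5, 44.5, by = 1), 45)
  expect_length(uni, 28L)
  expect_named(uni, ecg_feature_names())
  expect_equal(uni[["ecg_rr_mean"]], 1000)
  expect_equal(uni[["ecg_sdnn"]], 0)
  expect_equal(uni[["ecg_rmssd"]], 0)
  expect_equal(uni[["ecg_hr_mean"]], 60)

  # RR = 800, 850, 900 ms: RMSSD = sqrt((50^2 + 50^2) / 2) = 50
  hand <- extract_ecg_features(cumsum(c(0.5, 0.8, 0.85, 0.9)), 45)
  expect_equal(hand[["ecg_rmssd"]], 50)
  expect_equal(hand[["ecg_rr_mean"]], 850)

  few <- extract_ecg_features(c(0.5, 1.5), 45)
  expect_true(all(is.na(few)))
  expect_length(few, 28L)
})

test_that("EDA features: counts, constant case, and planted amplitude sum", {
  const <- rep(5, 450)
  f0 <- extract_eda_features(const, decompose_eda(const), 45)
  expect_length(f0, 63L)
  expect_named(f0, eda_feature_names())
  expect_equal(f0[["eda_scl_mean"]], 5)
  expect_equal(f0[["eda_scl_sd"]], 0)
  expect_equal(f0[["eda_scr_count"]], 0)
  expect_equal(f0[["eda_scr_rate"]], 0)
  expect_true(is.na(f0[["eda_scr_amp_mean"]]))

  # two planted SCRs of 0.3 and 0.5 uS: amplitude sum within 15% of 0.8
  base <- generate_eda(45, scr_rate_per_min = 0, noise_sd = 0.003,
                       seed = 2)$signal
  k <- trustdyn:::bateman_kernel(32)
  for (pp in list(c(8, 0.3), c(25, 0.5))) {
    i0 <- pp[1] * 32
    base[i0:(i0 + length(k) - 1)] <- base[i0:(i0 + length(k) - 1)] + pp[2] * k
  }
  cl <- clean_eda(base, 32)$signal
  f2 <- extract_eda_features(cl, decompose_eda(cl), 45)
  expect_equal(f2[["eda_scr_count"]], 2)
  expect_lt(abs(f2[["eda_scr_amp_sum"]] - 0.8) / 0.8, 0.15)
})

test_that("respiration features: counts, rate recovery, and symmetry", {
  r <- generate_resp(45, breath_rate_bpm = 15, seed = 3, noise_sd = 0.01)
  filt <- filter_resp(r$signal, 32)
  br <- detect_breaths(filt, 32)
  f <- extract_resp_features(filt, br$cycle_times, 32)
  expect_length(f, 28L)
  expect_named(f, rsp_feature_names())
  expect_lt(abs(f[["rsp_breath_rate"]] - 15), 0.5)
  expect_lt(abs(f[["rsp_ie_ratio"]] - 1), 0.2)  # symmetric waveform
  expect_true(all(is.na(extract_resp_features(filt, numeric(0), 32))))
})

test_that("EEG band powers agree with a direct-DFT oracle on a pure tone", {
  fs <- 250
  n <- 45 * fs
  t <- (0:(n - 1)) / fs
  sig <- matrix(rnorm(19 * n, 0, 0.05), 19)
  rownames(sig) <- trustdyn:::.eeg_channels
  amp <- 2
  sig[15, ] <- sig[15, ] + amp * sin(2 * pi * 10 * t)  # pz, alpha band
  f <- extract_eeg_features(sig, fs)
  expect_length(f, 125L)
  expect_named(f, eeg_feature_names())
  alpha <- f[["eeg_pz_alpha"]]
  others <- f[paste0("eeg_pz_", c("delta", "theta", "beta", "gamma"))]
  expect_true(all(alpha > 10 * others))
  # direct-DFT oracle: integrate the one-sided periodogram over 8-13 Hz
  x <- sig[15, ]
  px <- abs(fft(x - mean(x)))^2 / n^2
  freq <- (0:(n - 1)) * fs / n
  sel <- freq >= 8 & freq <= 13
  oracle <- 2 * sum(px[sel])
  expect_lt(abs(alpha - oracle) / oracle, 0.2)

  # identical channels: every region mean equals the channel value
  same <- matrix(rep(sig[15, ], each = 19), 19,
                 dimnames = list(trustdyn:::.eeg_channels, NULL))
  fs_same <- extract_eeg_features(same, fs)
  for (rg in c("prefrontal", "central", "whole")) {
    expect_equal(fs_same[[paste0("eeg_", rg, "_alpha")]],
                 fs_same[["eeg_pz_alpha"]], tolerance = 1e-10)
  }
})

test_that("fNIRS features: counts, zero case, and HRF peak timing", {
  zero <- list(hbo = matrix(0, 20, 450), hbr = matrix(0, 20, 450))
  f0 <- extract_fnirs_features(zero, 10)
  expect_length(f0, 360L)
  expect_named(f0, fnirs_feature_names())
  expect_equal(f0[["fnirs_ch01_hbo_mean"]], 0)
  expect_equal(f0[["fnirs_ch01_hbo_auc"]], 0)
  expect_equal(f0[["fnirs_ch01_hbr_slope"]], 0)

  # planted response peaking 6 s into the epoch
  k <- trustdyn:::hrf_kernel(10, peak_s = 6)
  hbo <- matrix(0, 20, 450)
  hbo[1, seq_along(k)] <- k
  f1 <- extract_fnirs_features(list(hbo = hbo, hbr = -0.4 * hbo), 10)
  expect_lt(abs(f1[["fnirs_ch01_hbo_ttmax"]] - 6), 0.5)
  expect_lt(abs(f1[["fnirs_ch01_hbr_ttmin"]] - 6), 0.5)
})

test_that("eye features: counts, degenerate cases, and AOI accounting", {
  empty_eye <- list(
    pupil = rep(3.5, 45 * 60), fs = 60,
    blinks = tibble::tibble(onset = numeric(0), duration = numeric(0)),
    fixations = tibble::tibble(onset = numeric(0), duration = numeric(0),
                               aoi = integer(0)),
    saccades = tibble::tibble(onset = numeric(0), duration = numeric(0),
                              amplitude = numeric(0)))
  f0 <- extract_eye_features(empty_eye, 45)
  expect_length(f0, 37L)
  expect_named(f0, eye_feature_names())
  expect_equal(f0[["eye_pupil_sd"]], 0)
  expect_equal(f0[["eye_blink_count"]], 0)
  expect_true(is.na(f0[["eye_aoi_entropy"]]))

  one_aoi <- empty_eye
  one_aoi$fixations <- tibble::tibble(onset = c(1, 2, 3),
                                      duration = c(0.5, 0.4, 0.3),
                                      aoi = c(2L, 2L, 2L))
  f1 <- extract_eye_features(one_aoi, 45)
  expect_equal(f1[["eye_dwell_aoi2"]], 1.2)
  expect_equal(f1[["eye_fixcount_aoi2"]], 3)
  expect_equal(f1[["eye_aoi_transitions"]], 0)
  expect_equal(f1[["eye_aoi_entropy"]], 0)

  ey <- generate_eye(45, seed = 5)
  f2 <- extract_eye_features(ey, 45)
  expect_equal(f2[["eye_blink_count"]], nrow(ey$blinks))
  expect_equal(f2[["eye_fix_count"]], nrow(ey$fixations))
})

test_that("embedded and background extraction mirror the dictionary order", {
  emb <- generate_embedded(c(0.4, 0.6), 2, 3, "high", seed = 1)
  rec <- extract_embedded(emb[1, ])
  expect_length(rec, 16L)
  expect_named(rec, embedded_feature_names())
  expect_equal(rec[["emb_session"]], 2)
  expect_equal(rec[["emb_trial"]], 3)
  expect_equal(rec[["emb_explainability"]], 1)
  # percent reviewed/ignored are complementary
  expect_equal(rec[["emb_pct_reviewed"]] + rec[["emb_pct_ignored"]], 100)
  bg <- generate_background(2, seed = 1)$background
  rb <- extract_background(bg[1, ])
  expect_length(rb, 25L)
  expect_named(rb, background_feature_names())
})
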