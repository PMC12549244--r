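test_that("ECG filter cascade removes mains, drift, and preserves phase", {
  fs <- 500
  t <- (0:22499) / fs
  mains <- sin(2 * pi * 60 * t)
  resid <- filter_ecg(mains, fs)
  expect_lt(max(abs(resid[2000:20000])), 0.01)  # < 1% of unit input
  dc <- filter_ecg(rep(1, 30 * fs), fs)
  expect_lt(max(abs(dc[(6 * fs):(24 * fs)])), 1e-5)
  # zero-phase contract: an in-band tone keeps its peak positions
  tone <- sin(2 * pi * 10 * t)
  out <- filter_ecg(tone, fs)
  core <- 1000:21000
  cc <- stats::ccf(out[core], tone[core], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_error(filter_ecg(tone, fs = 150), "fs > 200")
  expect_error(filter_ecg(c(1, NA, 2), fs = 500), "non-finite")
})

test_that("R-peak detection matches generator truth within 10 ms", {
  e <- generate_ecg(45, mean_hr_bpm = 60, hrv_sd_ms = 30, fs = 500, seed = 8)
  pk <- detect_r_peaks(filter_ecg(e$signal, 500), 500)
  expect_false(pk$flag)
  expect_lte(abs(length(pk$times) - length(e$r_times)), 1)
  err <- vapply(pk$times, function(x) min(abs(x - e$r_times)), numeric(1))
  expect_lt(mean(err) * 1000, 10)
  expect_true(all(diff(pk$times) > 0.2))  # refractory period

  z <- detect_r_peaks(rep(0, 5000), 500)
  expect_length(z$times, 0)
  expect_true(z$flag)

  # concatenated rates: per-half counts track truth
  e1 <- generate_ecg(45, mean_hr_bpm = 60, hrv_sd_ms = 0, fs = 500, seed = 1)
  e2 <- generate_ecg(45, mean_hr_bpm = 90, hrv_sd_ms = 0, fs = 500, seed = 2)
  both <- filter_ecg(c(e1$signal, e2$signal), 500)
  pk2 <- detect_r_peaks(both, 500)
  expect_lte(abs(sum(pk2$times < 45) - length(e1$r_times)), 1)
  expect_lte(abs(sum(pk2$times >= 45) - length(e2$r_times)), 1)
})

test_that("EDA cleaning interpolates artifacts, smooths, and resamples to 10 Hz", {
  const <- clean_eda(rep(5, 45 * 32), 32)
  expect_equal(const$signal, rep(5, 450), tolerance = 1e-6)
  expect_equal(length(const$signal), 450L)
  spiky <- rep(5, 45 * 32)
  spiky[700] <- 80
  cl <- clean_eda(spiky, 32)
  expect_lt(max(cl$signal), 41)
  expect_false(cl$flag)
  mostly_bad <- c(rep(0.1, 1000), rep(5, 400))
  expect_true(clean_eda(mostly_bad, 32)$flag)
})

test_that("EDA decomposition reconstructs and recovers planted SCRs", {
  # constant input: constant tonic, negligible phasic, no events
  dc0 <- decompose_eda(rep(5, 450))
  expect_equal(dc0$tonic, rep(5, 450), tolerance = 1e-6)
  expect_lt(max(abs(dc0$phasic)), 1e-6)
  expect_equal(nrow(dc0$scr_events), 0L)

  # one planted Bateman pulse: exactly one event within 15% amplitude
  ed <- generate_eda(45, scr_rate_per_min = 0, noise_sd = 0.003, seed = 1)
  k <- trustdyn:::bateman_kernel(32)
  sig <- ed$signal
  i0 <- 10 * 32
  sig[i0:(i0 + length(k) - 1)] <- sig[i0:(i0 + length(k) - 1)] + 0.5 * k
  dc1 <- decompose_eda(clean_eda(sig, 32)$signal)
  expect_equal(nrow(dc1$scr_events), 1L)
  expect_lt(abs(dc1$scr_events$amplitude - 0.5) / 0.5, 0.15)
  expect_true(all(dc1$scr_events$amplitude >= 0))

  # reconstruction bound on generated epochs
  for (s in 1:3) {
    e <- generate_eda(45, scr_rate_per_min = 4, seed = s)
    cl <- clean_eda(e$signal, 32)$signal
    dc <- decompose_eda(cl)
    err <- sqrt(mean((cl - dc$tonic - dc$phasic)^2))
    expect_lt(err, 0.02 * sd(cl))
    expect_true(all(dc$phasic > -1e-9))
  }
})

test_that("respiration filter passes breathing rates and rejects drift", {
  fs <- 32
  t <- (0:(45 * fs - 1)) / fs
  drift <- sin(2 * pi * 0.01 * t)
  out_d <- filter_resp(drift, fs)
  expect_lt(max(abs(out_d[300:1100])), 0.1)  # > 90% attenuation
  tone <- sin(2 * pi * 0.25 * t)  # 15 breaths/min
  out_t <- filter_resp(tone, fs)
  expect_lt(abs(max(out_t[300:1100]) - 1), 0.05)  # preserved within 5%
  expect_error(filter_resp(tone, fs = 4), "fs > 6")
})

test_that("breath detection recovers the generated rate", {
  r <- generate_resp(45, breath_rate_bpm = 15, seed = 2)
  br <- detect_breaths(filter_resp(r$signal, 32), 32)
  expect_false(br$flag)
  rate <- 60 / mean(diff(br$cycle_times))
  expect_lt(abs(rate - 15), 0.5)
  expect_true(all(diff(br$cycle_times) > 0))
  flat <- detect_breaths(rep(0, 1440), 32)
  expect_length(flat$cycle_times, 0)
  expect_true(flat$flag)
})

test_that("EEG preprocessing removes ocular components and only those", {
  # blink-free input: reconstruction equals the bandpassed signal
  g0 <- generate_eeg(45, fs = 250, seed = 5, blink_rate_per_min = 0)
  p0 <- preprocess_eeg(g0$signal, 250)
  ref <- preprocess_eeg(g0$signal, 250, run_ica = FALSE)
  expect_length(p0$rejected, 0)
  expect_equal(p0$signal, ref$signal, tolerance = 1e-8)

  # planted frontal blinks: frontal low-band power cut by >= 50%
  g1 <- generate_eeg(45, fs = 250, seed = 6, blink_rate_per_min = 20)
  p1 <- preprocess_eeg(g1$signal, 250)
  expect_gt(length(p1$rejected), 0)
  f1 <- preprocess_eeg(g1$signal, 250, run_ica = FALSE)$signal
  lowpow <- function(m) mean(vapply(1:2, function(ci)
    trustdyn:::band_power(trustdyn:::welch_psd(m[ci, ], 250, 500), 0.5, 4),
    numeric(1)))
  expect_lt(lowpow(p1$signal), 0.5 * lowpow(f1))
  # posterior alpha untouched by the rejection
  alpha <- function(m, ci) trustdyn:::band_power(
    trustdyn:::welch_psd(m[ci, ], 250, 500), 8, 13)
  expect_equal(alpha(p1$signal, 15), alpha(f1, 15), tolerance = 0.05)

  # 60 Hz contamination attenuated by the 55 Hz edge
  t <- (0:11249) / 250
  g2 <- g0$signal + matrix(rep(5 * sin(2 * pi * 60 * t), each = 19), 19)
  p2 <- preprocess_eeg(g2, 250, run_ica = FALSE)
  amp60 <- function(m) sqrt(trustdyn:::band_power(
    trustdyn:::welch_psd(m[1, ], 250, 1024), 59.5, 60.5))
  expect_lt(amp60(p2$signal), 0.5 * amp60(g2))
  expect_error(preprocess_eeg(g0$signal[1:5, ], 250), "19-channel")
})

test_that("fNIRS filter removes drift and cardiac ripple, keeps the HRF band", {
  fs <- 10
  # the drift check needs a window longer than the 0.016 Hz edge period
  tl <- (0:(240 * fs - 1)) / fs
  ramp <- matrix(rep(tl / 240, each = 20), 20)  # unit linear trend
  out_r <- filter_fnirs(ramp, ramp, fs)
  core <- (60 * fs):(180 * fs)
  slope_in <- trustdyn:::series_slope(ramp[1, core], fs)
  slope_out <- trustdyn:::series_slope(out_r$hbo[1, core], fs)
  expect_lt(abs(slope_out), 0.05 * abs(slope_in))
  t <- (0:449) / fs
  card <- matrix(rep(sin(2 * pi * 1 * t), each = 20), 20)
  out_c <- filter_fnirs(card, card, fs)
  expect_lt(max(abs(out_c$hbo[1, 100:350])), 0.1)
  hrf_band <- matrix(rep(sin(2 * pi * 0.1 * t), each = 20), 20)
  out_h <- filter_fnirs(hrf_band, hrf_band, fs)
  expect_lt(abs(max(out_h$hbo[1, 100:350]) - 1), 0.1)
  expect_error(filter_fnirs(ramp, ramp, fs = 0.9), "fs > 1")
})
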