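# Per-stream feature extractors.  Each returns a named numeric vector with
# exactly the dictionary's count for that category; quantities that cannot
# be computed (too few events, zero variance) are NA and flow into the
# hierarchical imputation.

na_features <- function(names) setNames(rep(NA_real_, length(names)), names)

#' Extract ECG features from detected R-peaks
#'
#' 16 time-domain R-R statistics, 9 frequency-domain measures (Welch PSD of
#' the 4 Hz-resampled R-R series; VLF 0.0033-0.04, LF 0.04-0.15,
#' HF 0.15-0.4 Hz), and 3 Poincare descriptors.  Fewer than 3 peaks flags
#' all 28 features missing.
#'
#' @param r_times R-peak times in seconds.
#' @param epoch_s Window duration in seconds.
#' @return Named numeric vector of length 28.
#' @export
extract_ecg_features <- function(r_times, epoch_s) {
  nms <- ecg_feature_names()
  if (length(r_times) < 3L) return(na_features(nms))
  rr <- diff(r_times) * 1000  # ms
  drr <- diff(rr)
  hr <- 60000 / rr
  sdnn <- sd(rr)
  sd1 <- if (length(drr) >= 2L) sd(drr) / sqrt(2) else NA_real_
  sd2 <- if (is.finite(sd1)) sqrt(max(2 * sdnn^2 - sd1^2, 0)) else NA_real_
  # frequency domain on the 4 Hz-interpolated R-R series
  freq <- rep(NA_real_, 9)
  names(freq) <- c("vlf", "lf", "hf", "tot", "ratio", "lfnu", "hfnu",
                   "lfpk", "hfpk")
  if (length(rr) >= 4L) {
    mid <- (r_times[-1] + r_times[-length(r_times)]) / 2
    tt <- seq(0, epoch_s, by = 0.25)
    rri <- approx(mid, rr, xout = tt, rule = 2)$y
    # single long segment: the low-frequency bands need fine resolution
    w <- welch_psd(rri - mean(rri), fs = 4, nperseg = length(rri))
    vlf <- band_power(w, 0.0033, 0.04)
    lf <- band_power(w, 0.04, 0.15)
    hf <- band_power(w, 0.15, 0.4)
    pk <- function(lo, hi) {
      sel <- which(w$freq >= lo & w$freq <= hi)
      if (!length(sel)) return(NA_real_)
      w$freq[sel[which.max(w$psd[sel])]]
    }
    freq <- c(vlf = vlf, lf = lf, hf = hf, tot = vlf + lf + hf,
              ratio = if (hf > 0) lf / hf else NA_real_,
              lfnu = if (lf + hf > 0) 100 * lf / (lf + hf) else NA_real_,
              hfnu = if (lf + hf > 0) 100 * hf / (lf + hf) else NA_real_,
              lfpk = pk(0.04, 0.15), hfpk = pk(0.15, 0.4))
  }
  vals <- c(
    mean(rr), median(rr), sdnn,
    if (length(drr) >= 1L) sqrt(mean(drr^2)) else NA_real_,  # RMSSD
    if (length(drr) >= 2L) sd(drr) else NA_real_,            # SDSD
    if (length(drr) >= 1L) 100 * mean(abs(drr) > 50) else NA_real_,
    if (length(drr) >= 1L) 100 * mean(abs(drr) > 20) else NA_real_,
    min(rr), max(rr), diff(range(rr)),
    if (mean(rr) > 0) sdnn / mean(rr) else NA_real_,
    mean(hr), min(hr), max(hr), skewness(rr), kurtosis(rr),
    freq[["vlf"]], freq[["lf"]], freq[["hf"]], freq[["tot"]],
    freq[["ratio"]], freq[["lfnu"]], freq[["hfnu"]],
    freq[["lfpk"]], freq[["hfpk"]],
    sd1, sd2,
    if (is.finite(sd1) && is.finite(sd2) && sd2 > 0) sd1 / sd2 else NA_real_
  )
  setNames(vals, nms)
}

stat9_of <- function(x, fs) {
  c(mean = mean(x), sd = sd(x), min = min(x), max = max(x),
    range = diff(range(x)), slope = series_slope(x, fs),
    auc = series_auc(x, fs), skew = skewness(x), kurtosis = kurtosis(x))
}

#' Extract EDA features
#'
#' Nine summary statistics over each of the cleaned skin conductance, tonic,
#' phasic, and phasic-driver series and the first derivative of the cleaned
#' signal (45), plus 18 SCR-event measures.  Zero-SCR epochs report
#' `count = 0`, `rate = 0`, and missing event statistics.
#'
#' @param clean10 Cleaned 10 Hz skin conductance.
#' @param decomp A [decompose_eda()] result.
#' @param epoch_s Window duration in seconds.
#' @return Named numeric vector of length 63.
#' @export
extract_eda_features <- function(clean10, decomp, epoch_s) {
  fs <- 10
  deriv <- c(diff(clean10), 0) * fs
  series <- list(scl = clean10, tonic = decomp$tonic,
                 phasic = decomp$phasic, driver = decomp$driver,
                 deriv = deriv)
  stat_vals <- unlist(lapply(series, stat9_of, fs = fs))
  ev <- decomp$scr_events
  k <- nrow(ev)
  s_or_na <- function(x, f) if (length(x[is.finite(x)]) > 0) f(x[is.finite(x)]) else NA_real_
  amp <- ev$amplitude; rise <- ev$rise_time; rec <- ev$half_recovery
  isi <- if (k >= 2) diff(ev$onset) else numeric(0)
  scr_vals <- c(
    k, k / epoch_s * 60,
    s_or_na(amp, mean), if (k >= 2) sd(amp) else NA_real_,
    s_or_na(amp, max), s_or_na(amp, min), if (k > 0) sum(amp) else NA_real_,
    s_or_na(rise, mean), if (k >= 2) sd(rise) else NA_real_, s_or_na(rise, max),
    s_or_na(rec, mean),
    if (sum(is.finite(rec)) >= 2) sd(rec[is.finite(rec)]) else NA_real_,
    s_or_na(rec, max),
    if (k > 0) ev$onset[1] else NA_real_,
    series_auc(decomp$phasic, fs),
    s_or_na(isi, mean), if (length(isi) >= 2) sd(isi) else NA_real_,
    mean(decomp$phasic > 0.01)
  )
  setNames(c(stat_vals, scr_vals), eda_feature_names())
}

#' Extract respiration features
#'
#' Breath-interval statistics, per-cycle amplitude statistics, inhale/exhale
#' durations, whole-signal statistics, and the dominant spectral frequency.
#' Fewer than 2 detected cycles flags all 28 features missing.
#'
#' @param filtered Filtered respiration waveform.
#' @param cycle_times Breath-cycle onset times (s).
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector of length 28.
#' @export
extract_resp_features <- function(filtered, cycle_times, fs) {
  nms <- rsp_feature_names()
  if (length(cycle_times) < 2L) return(na_features(nms))
  bi <- diff(cycle_times)
  n_cyc <- length(bi)
  amp <- inhale <- exhale <- rep(NA_real_, n_cyc)
  for (i in seq_len(n_cyc)) {
    i0 <- floor(cycle_times[i] * fs) + 1L
    i1 <- min(length(filtered), floor(cycle_times[i + 1] * fs))
    if (i1 - i0 < 3L) next
    seg <- filtered[i0:i1]
    amp[i] <- diff(range(seg))
    # inhale = trough-to-peak duration (circular within the cycle)
    pk <- which.max(seg)
    tr <- which.min(seg)
    inh <- ((pk - tr) %% length(seg)) / fs
    inhale[i] <- inh
    exhale[i] <- (i1 - i0 + 1) / fs - inh
  }
  w <- welch_psd(filtered - mean(filtered), fs)
  sel <- which(w$freq >= 0.05 & w$freq <= 3)
  dom <- if (length(sel)) w$freq[sel[which.max(w$psd[sel])]] else NA_real_
  ok <- is.finite(amp)
  vals <- c(
    mean(bi), sd(bi), min(bi), max(bi), diff(range(bi)),
    if (mean(bi) > 0) sd(bi) / mean(bi) else NA_real_,
    skewness(bi), kurtosis(bi), 60 / mean(bi),
    mean(amp[ok]), if (sum(ok) >= 2) sd(amp[ok]) else NA_real_,
    suppressWarnings(min(amp[ok])), suppressWarnings(max(amp[ok])),
    if (sum(ok) >= 1) diff(range(amp[ok])) else NA_real_,
    if (sum(ok) >= 2 && mean(amp[ok]) > 0) sd(amp[ok]) / mean(amp[ok]) else NA_real_,
    mean(inhale[ok]), if (sum(ok) >= 2) sd(inhale[ok]) else NA_real_,
    mean(exhale[ok]), if (sum(ok) >= 2) sd(exhale[ok]) else NA_real_,
    if (sum(ok) >= 1 && mean(exhale[ok]) > 0)
      mean(inhale[ok]) / mean(exhale[ok]) else NA_real_,
    mean(filtered), sd(filtered), skewness(filtered), kurtosis(filtered),
    rms(filtered), series_slope(filtered, fs), series_auc(filtered, fs),
    dom
  )
  setNames(vals, nms)
}

#' Extract EEG band-power features
#'
#' Welch PSD band power (uV^2) for the five canonical bands on each of the
#' 19 channels, plus the six regional means (prefrontal, central, parietal,
#' occipital, temporal, whole head).  Gamma is integrated over 30-55 Hz, up
#' to the preprocessing lowpass edge.
#'
#' @param cleaned Channels x samples matrix with 10-20 rownames.
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector of length 125.
#' @export
extract_eeg_features <- function(cleaned, fs) {
  assert_that(is.matrix(cleaned) && nrow(cleaned) == 19L,
              "extract_eeg_features expects a 19-channel matrix")
  channels <- rownames(cleaned) %||% .eeg_channels
  powers <- matrix(NA_real_, 19, 5, dimnames = list(channels, .eeg_bands))
  for (ci in seq_len(19)) {
    w <- welch_psd(cleaned[ci, ], fs, nperseg = round(2 * fs))
    for (b in .eeg_bands) {
      e <- .eeg_band_edges[[b]]
      powers[ci, b] <- band_power(w, e[1], e[2])
    }
  }
  chan_vals <- as.vector(t(powers))
  region_vals <- unlist(lapply(names(.eeg_regions), function(rg) {
    colMeans(powers[.eeg_regions[[rg]], , drop = FALSE])
  }))
  setNames(c(chan_vals, region_vals), eeg_feature_names())
}

fnirs_channel_features <- function(x, fs, type) {
  n <- length(x)
  tt <- (seq_len(n) - 1) / fs
  extreme <- if (type == "hbo") max(x) else min(x)
  t_ext <- tt[if (type == "hbo") which.max(x) else which.min(x)]
  c(extreme, t_ext, mean(x), var(x), skewness(x), kurtosis(x), rms(x),
    series_slope(x, fs), series_auc(x, fs))
}

#' Extract fNIRS features
#'
#' Per channel: HbO maximum amplitude and time-to-maximum, HbR minimum
#' amplitude and time-to-minimum, and for both species the mean, variance,
#' skew, kurtosis, RMS, slope, and area under the curve (18 features x 20
#' channels).
#'
#' @param filtered A [filter_fnirs()] result (`hbo`, `hbr` matrices).
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector of length 360.
#' @export
extract_fnirs_features <- function(filtered, fs) {
  n_ch <- nrow(filtered$hbo)
  assert_that(n_ch == nrow(filtered$hbr), "channel count mismatch")
  vals <- unlist(lapply(seq_len(n_ch), function(ci) {
    c(fnirs_channel_features(filtered$hbo[ci, ], fs, "hbo"),
      fnirs_channel_features(filtered$hbr[ci, ], fs, "hbr"))
  }))
  setNames(vals, fnirs_feature_names(n_ch))
}

#' Extract eye-tracking features
#'
#' 21 pupil/blink features (pupil statistics, constriction/dilation
#' velocities, blink counts, durations, inter-blink intervals, eye-closure
#' fraction) and 16 fixation/saccade features (per-AOI dwell and counts,
#' fixation durations, saccade statistics, AOI transition count and
#' entropy).
#'
#' @param eye A [generate_eye()]-shaped bundle (`pupil`, `fs`, `blinks`,
#'   `fixations`, `saccades`).
#' @param epoch_s Window duration in seconds.
#' @return Named numeric vector of length 37.
#' @export
extract_eye_features <- function(eye, epoch_s) {
  p <- eye$pupil
  fs <- eye$fs
  v <- diff(p) * fs
  b <- eye$blinks
  fx <- eye$fixations
  sc <- eye$saccades
  nb <- nrow(b); nf <- nrow(fx); ns <- nrow(sc)
  ibi <- if (nb >= 2) diff(b$onset) else numeric(0)
  dwell <- vapply(1:4, function(a) sum(fx$duration[fx$aoi == a]), numeric(1))
  fixn <- vapply(1:4, function(a) sum(fx$aoi == a), numeric(1))
  trans <- if (nf >= 2) sum(diff(fx$aoi) != 0) else 0
  # no fixations at all: entropy unobservable; fixations without AOI
  # changes: zero-entropy transition pattern
  ent <- if (nf == 0) NA_real_ else if (trans == 0) 0 else {
    dest <- fx$aoi[-1][diff(fx$aoi) != 0]
    shannon_entropy(table(dest))
  }
  vals <- c(
    mean(p), sd(p), min(p), max(p), diff(range(p)), series_slope(p, fs),
    skewness(p), kurtosis(p), rms(p),
    min(v), max(v), mean(abs(v)),
    nb, nb / epoch_s * 60,
    if (nb > 0) mean(b$duration) else NA_real_,
    if (nb >= 2) sd(b$duration) else NA_real_,
    if (nb > 0) min(b$duration) else NA_real_,
    if (nb > 0) max(b$duration) else NA_real_,
    if (length(ibi)) mean(ibi) else NA_real_,
    if (length(ibi) >= 2) sd(ibi) else NA_real_,
    sum(b$duration) / epoch_s,
    dwell, fixn,
    if (nf > 0) mean(fx$duration) else NA_real_,
    if (nf >= 2) sd(fx$duration) else NA_real_,
    nf, ns, ns / epoch_s * 60,
    if (ns > 0) mean(sc$amplitude) else NA_real_,
    trans, ent
  )
  setNames(vals, eye_feature_names())
}

#' Extract embedded task measures for an epoch
#'
#' The embedded measures are logged directly by the task, so extraction
#' selects and orders the 16 dictionary columns from an epoch's embedded
#' record.
#'
#' @param record A one-row tibble/list with the `emb_*` columns.
#' @return Named numeric vector of length 16.
#' @export
extract_embedded <- function(record) {
  nms <- embedded_feature_names()
  out <- vapply(nms, function(nm) as.numeric(record[[nm]]), numeric(1))
  setNames(out, nms)
}

#' Extract operator background features for a participant
#'
#' @param record A one-row tibble/list with the `bg_*` columns.
#' @return Named numeric vector of length 25.
#' @export
extract_background <- function(record) {
  nms <- background_feature_names()
  out <- vapply(nms, function(nm) as.numeric(record[[nm]]), numeric(1))
  setNames(out, nms)
}
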