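# Stream cleaning: ECG filter cascade and R-peak detection, EDA cleaning and
# tonic/phasic decomposition, respiration filtering and breath detection.
# All filters are 4th-order Butterworth applied forward-backward (zero phase).

butter_filtfilt <- function(x, fs, w, type) {
  bf <- signal::butter(4, w / (fs / 2), type = type)
  signal::filtfilt(bf, x)
}

#' Filter a raw ECG waveform
#'
#' Zero-phase cascade: 1 Hz highpass (baseline drift), 100 Hz lowpass
#' (electromyographic noise), 59-61 Hz Butterworth bandstop (powerline).
#'
#' @param raw Numeric waveform (mV).
#' @param fs Sampling rate in Hz; must exceed 200 Hz so the 100 Hz lowpass
#'   edge is below Nyquist.
#' @return Filtered waveform, same length as the input.
#' @export
filter_ecg <- function(raw, fs) {
  assert_that(fs > 200, "filter_ecg requires fs > 200 Hz")
  assert_that(all(is.finite(raw)), "non-finite samples in ECG input")
  x <- butter_filtfilt(raw, fs, 1, "high")
  x <- butter_filtfilt(x, fs, 100, "low")
  butter_filtfilt(x, fs, c(59, 61), "stop")
}

#' Detect R-peaks in a filtered ECG
#'
#' Threshold detector on the filtered signal with local-maximum refinement
#' and a 200 ms refractory period.  A flat or peak-free input returns an
#' empty event list with a quality flag rather than an error.
#'
#' @param clean Filtered ECG waveform.
#' @param fs Sampling rate in Hz.
#' @return List with `times` (strictly increasing R-peak times in s),
#'   `flag` (`TRUE` when detection looks unreliable), and `threshold`.
#' @export
detect_r_peaks <- function(clean, fs) {
  n <- length(clean)
  s <- sd(clean)
  if (!is.finite(s) || s < 1e-9) {
    return(list(times = numeric(0), flag = TRUE, threshold = NA_real_))
  }
  thr <- 0.5 * quantile(clean, 0.999, names = FALSE)
  if (thr <= 4 * s / 3) thr <- 4 * s  # no clear QRS prominence
  refr <- round(0.2 * fs)
  cand <- which(clean > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[clean[cand] >= clean[cand - 1] & clean[cand] >= clean[cand + 1]]
  if (length(cand) == 0L) {
    return(list(times = numeric(0), flag = TRUE, threshold = thr))
  }
  peaks <- integer(0)
  for (i in cand) {
    if (length(peaks) && i - peaks[length(peaks)] < refr) {
      # keep the taller of the two within the refractory window
      if (clean[i] > clean[peaks[length(peaks)]]) peaks[length(peaks)] <- i
    } else {
      peaks <- c(peaks, i)
    }
  }
  times <- (peaks - 1) / fs
  flag <- length(peaks) < 3L
  list(times = times, flag = flag, threshold = thr)
}

#' Clean a raw EDA waveform
#'
#' Samples outside the physiological 1-40 uS range are treated as motion
#' artifacts and replaced by linear interpolation from their neighbors, the
#' series is smoothed with a 3rd-order Savitzky-Golay filter, and the result
#' is resampled to 10 Hz for decomposition.
#'
#' @param raw Numeric waveform (uS).
#' @param fs Sampling rate in Hz (>= 10).
#' @return List with `signal` (10 Hz), `fs` (10), and `flag` (`TRUE` when
#'   more than half the samples were out of range, marking the epoch
#'   unusable for EDA).
#' @export
clean_eda <- function(raw, fs) {
  assert_that(fs >= 10, "clean_eda requires fs >= 10 Hz")
  n <- length(raw)
  bad <- !is.finite(raw) | raw < 1 | raw > 40
  flag <- mean(bad) > 0.5
  x <- raw
  if (any(bad)) {
    if (all(bad)) {
      x[] <- 1
    } else {
      x[bad] <- approx(which(!bad), x[!bad], xout = which(bad),
                       rule = 2)$y
    }
  }
  win <- max(5L, round(fs / 4))
  if (win %% 2L == 0L) win <- win + 1L
  x <- signal::sgolayfilt(x, p = 3, n = win)
  t_in <- (seq_len(n) - 1) / fs
  t_out <- seq(0, (n - 1) / fs, by = 0.1)
  out <- approx(t_in, x, xout = t_out, rule = 2)$y
  list(signal = out, fs = 10, flag = flag)
}

# Discrete Bateman kernel poles at the decomposition rate.
.bateman_poles <- function(fs, tau_rise, tau_decay) {
  list(a_slow = exp(-1 / (fs * tau_decay)), a_fast = exp(-1 / (fs * tau_rise)))
}

#' Decompose a cleaned 10 Hz EDA signal into tonic and phasic components
#'
#' The Bateman SCR kernel is an ARMA(2,1) impulse response, so deconvolution
#' is an exact 3-tap inverse filter.  The raw driver is split into a smooth
#' tonic floor (running-quantile envelope) and a non-negative phasic driver;
#' the phasic component is the driver re-convolved with the kernel and the
#' tonic component is the remainder, so `tonic + phasic` reconstructs the
#' input exactly.  SCR events are driver pulses whose peak phasic
#' contribution exceeds 0.01 uS.
#'
#' @param clean10 Cleaned EDA at 10 Hz, at least 30 s long.
#' @param tau_rise,tau_decay Bateman time constants (s).
#' @return List with `tonic`, `phasic`, `driver` (phasic driver), and
#'   `scr_events` (tibble: `onset`, `amplitude`, `rise_time`,
#'   `half_recovery`; `half_recovery` is `NA` when not reached in-window).
#' @export
decompose_eda <- function(clean10, tau_rise = 0.75, tau_decay = 2) {
  fs <- 10
  n <- length(clean10)
  assert_that(n >= 30 * fs, "decompose_eda requires at least 30 s of input")
  p <- .bateman_poles(fs, tau_rise, tau_decay)
  a1 <- p$a_slow; a2 <- p$a_fast
  kmax_t <- log(tau_decay / tau_rise) * tau_decay * tau_rise /
    (tau_decay - tau_rise)
  M <- exp(-kmax_t / tau_decay) - exp(-kmax_t / tau_rise)
  # exact inverse filter of the unit-peak kernel (one-sample advance)
  y <- clean10
  d_raw <- rep(0, n)
  i <- 2:(n - 1)
  d_raw[i] <- M * (y[i + 1] - (a1 + a2) * y[i] + a1 * a2 * y[i - 1]) /
    (a1 - a2)
  d_raw[1] <- d_raw[2]; d_raw[n] <- d_raw[n - 1]
  # tonic driver floor: running median (SCR impulses are brief and sparse,
  # so the windowed median tracks the tonic-driven baseline), smoothed
  win <- 4 * fs + 1
  floor_env <- stats::runmed(d_raw, win, endrule = "median")
  floor_env <- signal::sgolayfilt(floor_env, p = 2,
                                  n = 2 * fs + 1)
  # 3-sample smoothing suppresses single-sample deconvolution noise
  d_sm <- stats::filter(d_raw - floor_env, rep(1 / 3, 3), sides = 2)
  d_sm[is.na(d_sm)] <- 0
  pd <- pmax(as.numeric(d_sm), 0)
  resid_mad <- stats::mad(d_sm)
  eps <- max(4 * resid_mad, 1e-9)
  pd[pd < eps] <- 0
  kern <- bateman_kernel(fs, tau_rise, tau_decay)
  phasic <- conv_trunc(pd, kern, n)
  tonic <- y - phasic
  scr_events <- scr_events_from_driver(pd, kern, fs)
  list(tonic = tonic, phasic = phasic, driver = pd, scr_events = scr_events)
}

conv_trunc <- function(x, k, n) fft_conv(x, k)[seq_len(n)]

# Segment the non-negative phasic driver into pulses and characterize each
# as an SCR event.
scr_events_from_driver <- function(pd, kern, fs, amp_threshold = 0.01) {
  n <- length(pd)
  active <- pd > 0
  if (!any(active)) {
    return(tibble(onset = numeric(0), amplitude = numeric(0),
                  rise_time = numeric(0), half_recovery = numeric(0)))
  }
  # merge active runs separated by < 0.5 s
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble(start = starts[r$values], end = ends[r$values])
  merged <- list()
  cur <- runs[1, ]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs$start[i] - cur$end <= 0.5 * fs) {
      cur$end <- runs$end[i]
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- runs[i, ]
    }
  }
  merged[[length(merged) + 1L]] <- cur
  runs <- purrr::list_rbind(merged)
  ev <- purrr::pmap(runs, function(start, end) {
    seg <- numeric(n)
    seg[start:end] <- pd[start:end]
    contrib <- conv_trunc(seg, kern, n)
    pk <- which.max(contrib)
    amp <- contrib[pk]
    if (amp < amp_threshold) return(NULL)
    onset <- (start - 1) / fs
    rise <- (pk - start) / fs
    after <- which(contrib[pk:n] < amp / 2)
    half_rec <- if (length(after)) (after[1] - 1) / fs else NA_real_
    tibble(onset = onset, amplitude = amp, rise_time = rise,
           half_recovery = half_rec)
  })
  ev <- purrr::list_rbind(purrr::compact(ev))
  if (nrow(ev) == 0L) {
    return(tibble(onset = numeric(0), amplitude = numeric(0),
                  rise_time = numeric(0), half_recovery = numeric(0)))
  }
  arrange(ev, .data$onset)
}

#' Filter a raw respiration waveform
#'
#' Zero-phase 0.05-3 Hz Butterworth bandpass, preserving breathing rates
#' between 3 and 180 breaths per minute while removing baseline drift and
#' high-frequency noise.
#'
#' @param raw Numeric waveform.
#' @param fs Sampling rate in Hz (> 6).
#' @return Filtered waveform, same length as input.
#' @export
filter_resp <- function(raw, fs) {
  assert_that(fs > 6, "filter_resp requires fs > 6 Hz")
  butter_filtfilt(raw, fs, c(0.05, 3), "pass")
}

#' Detect breath cycles in a filtered respiration signal
#'
#' Cycle onsets are upward zero crossings of the mean-removed filtered
#' signal, with a minimum cycle spacing of 1/3 s (180 breaths/min).
#'
#' @param filtered Filtered respiration waveform.
#' @param fs Sampling rate in Hz.
#' @return List with `cycle_times` (strictly increasing onset times, s) and
#'   `flag` (`TRUE` when no cycles were found).
#' @export
detect_breaths <- function(filtered, fs) {
  x <- filtered - mean(filtered)
  if (sd(x) < 1e-9) return(list(cycle_times = numeric(0), flag = TRUE))
  up <- which(x[-length(x)] < 0 & x[-1] >= 0)
  if (length(up) == 0L) return(list(cycle_times = numeric(0), flag = TRUE))
  times <- up / fs
  keep <- c(TRUE, diff(times) >= 1 / 3)
  # enforce the spacing iteratively (rare with clean signals)
  while (!all(keep)) {
    times <- times[keep]
    keep <- c(TRUE, diff(times) >= 1 / 3)
  }
  list(cycle_times = times, flag = FALSE)
}

#' Filter fNIRS hemoglobin series
#'
#' Zero-phase 0.016-0.5 Hz Butterworth bandpass applied independently to
#' every HbO and HbR channel, removing linear drift and cardiac artifacts.
#'
#' @param hbo,hbr Channel-by-sample matrices (uM).
#' @param fs Sampling rate in Hz (> 1 so the 0.5 Hz upper edge is below
#'   Nyquist).
#' @return List with filtered `hbo` and `hbr` matrices.
#' @export
filter_fnirs <- function(hbo, hbr, fs) {
  assert_that(fs > 1, "filter_fnirs requires fs > 1 Hz")
  assert_that(nrow(hbo) == nrow(hbr) && ncol(hbo) == ncol(hbr),
              "hbo and hbr must have matching dimensions")
  bf <- signal::butter(4, c(0.016, 0.5) / (fs / 2), type = "pass")
  f <- function(m) t(apply(m, 1, function(x) signal::filtfilt(bf, x)))
  list(hbo = f(hbo), hbr = f(hbr))
}
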