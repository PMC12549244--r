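# Raw-signal generators.  Each returns the waveform plus its ground truth so
# downstream estimates (R-peak times, SCR amplitudes, band powers, ...) can be
# checked against what was planted.

#' Generate a synthetic ECG waveform
#'
#' Places P-QRS-T complexes at R-R intervals drawn from a (truncated) normal
#' distribution, then adds baseline wander, powerline interference, and
#' broadband noise.  The true R-peak times are returned alongside the
#' waveform.
#'
#' @param duration_s Duration in seconds (must cover at least one beat).
#' @param mean_hr_bpm Mean heart rate, 30-200 bpm.
#' @param hrv_sd_ms SD of successive R-R intervals in milliseconds.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param mains_amp Amplitude (mV) of the 60 Hz powerline component.
#' @param wander_amp Amplitude (mV) of the ~0.15 Hz baseline wander.
#' @param noise_sd SD (mV) of additive white noise.
#' @return A list with `signal` (mV), `fs`, `r_times` (s), `rr_s`
#'   (true R-R intervals, s), and `params`.
#' @export
generate_ecg <- function(duration_s, mean_hr_bpm = 70, hrv_sd_ms = 40,
                         fs = 500, seed = 1, mains_amp = 0.05,
                         wander_amp = 0.1, noise_sd = 0.02) {
  assert_that(mean_hr_bpm >= 30 && mean_hr_bpm <= 200,
              "mean_hr_bpm must be within 30-200 bpm")
  mean_rr <- 60 / mean_hr_bpm
  assert_that(duration_s >= mean_rr,
              "duration_s must cover at least one beat")
  with_seed(seed, {
    n_max <- ceiling(duration_s / mean_rr * 2) + 10L
    rr <- rnorm(n_max, mean_rr, hrv_sd_ms / 1000)
    rr <- pmax(rr, 0.3)
    r_times <- cumsum(rr)
    keep <- r_times <= duration_s - 0.05
    r_times <- r_times[keep]
    rr <- rr[keep]
    n <- round(duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    # P-QRS-T template (offset s, width s, amplitude mV per wave), placed at
    # every beat by FFT convolution with an impulse train
    waves <- list(
      c(-0.20, 0.050, 0.10),   # P
      c(-0.035, 0.010, -0.15), # Q
      c(0.000, 0.008, 1.00),   # R
      c(0.035, 0.010, -0.20),  # S
      c(0.250, 0.070, 0.30)    # T
    )
    pre_s <- 0.45
    tt <- seq(-pre_s, 0.6, by = 1 / fs)
    template <- Reduce(`+`, lapply(waves, function(w)
      w[3] * exp(-((tt - w[1])^2) / (2 * w[2]^2))))
    imp <- numeric(n)
    beat_idx <- round(r_times * fs) + 1L
    imp[beat_idx[beat_idx >= 1 & beat_idx <= n]] <- 1
    full <- fft_conv(imp, template)
    offset <- round(pre_s * fs)
    signal <- full[(offset + 1):(offset + n)]
    signal <- signal +
      wander_amp * sin(2 * pi * 0.15 * t + runif(1, 0, 2 * pi)) +
      mains_amp * sin(2 * pi * 60 * t) +
      rnorm(n, 0, noise_sd)
    list(signal = signal, fs = fs, r_times = r_times, rr_s = rr,
         params = list(mean_hr_bpm = mean_hr_bpm, hrv_sd_ms = hrv_sd_ms,
                       seed = seed))
  })
}

# Discrete Bateman kernel (skin conductance response shape), unit peak.
bateman_kernel <- function(fs, tau_rise = 0.75, tau_decay = 2,
                           length_s = 20) {
  t <- seq(0, length_s, by = 1 / fs)
  k <- exp(-t / tau_decay) - exp(-t / tau_rise)
  k / max(k)
}

#' Generate a synthetic electrodermal activity waveform
#'
#' Slow tonic drift plus Bateman-shaped skin conductance responses (SCRs) at
#' Poisson-distributed times.  Each SCR is scaled so its peak contribution
#' equals the drawn amplitude; the true tonic series and SCR event list are
#' returned.
#'
#' @param duration_s Duration in seconds.
#' @param tonic_level_uS Mean skin conductance level, 1-40 microsiemens.
#' @param scr_rate_per_min Poisson rate of SCR events per minute.
#' @param scr_amp_uS Typical SCR peak amplitude (log-normal spread around it).
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param drift_slope_uS_min Linear tonic drift in uS per minute.
#' @param noise_sd Additive noise SD in uS.
#' @param tau_rise,tau_decay Bateman time constants (s).
#' @return List with `signal`, `fs`, `tonic` (true tonic series),
#'   `scr_events` (tibble: `time`, `amplitude`), and `params`.
#' @export
generate_eda <- function(duration_s, tonic_level_uS = 8,
                         scr_rate_per_min = 4, scr_amp_uS = 0.5,
                         fs = 32, seed = 1, drift_slope_uS_min = 0,
                         noise_sd = 0.01, tau_rise = 0.75, tau_decay = 2) {
  assert_that(tonic_level_uS >= 1 && tonic_level_uS <= 40,
              "tonic_level_uS must be within 1-40 uS")
  assert_that(scr_rate_per_min >= 0, "scr_rate_per_min must be non-negative")
  assert_that(scr_amp_uS >= 0, "scr_amp_uS must be non-negative")
  with_seed(seed, {
    n <- round(duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    tonic <- tonic_level_uS + drift_slope_uS_min * t / 60 +
      0.15 * sin(2 * pi * t / 90 + runif(1, 0, 2 * pi))
    n_scr <- rpois(1, scr_rate_per_min * duration_s / 60)
    signal <- tonic
    if (n_scr > 0) {
      times <- sort(runif(n_scr, 0, max(duration_s - 3, duration_s * 0.5)))
      amps <- scr_amp_uS * exp(rnorm(n_scr, 0, 0.2))
      k <- bateman_kernel(fs, tau_rise, tau_decay)
      for (i in seq_len(n_scr)) {
        i0 <- floor(times[i] * fs) + 1L
        idx <- i0:min(n, i0 + length(k) - 1L)
        signal[idx] <- signal[idx] + amps[i] * k[seq_along(idx)]
      }
      events <- tibble(time = times, amplitude = amps)
    } else {
      events <- tibble(time = numeric(), amplitude = numeric())
    }
    signal <- signal + rnorm(n, 0, noise_sd)
    list(signal = signal, fs = fs, tonic = tonic, scr_events = events,
         params = list(tonic_level_uS = tonic_level_uS,
                       scr_rate_per_min = scr_rate_per_min,
                       scr_amp_uS = scr_amp_uS,
                       drift_slope_uS_min = drift_slope_uS_min,
                       tau_rise = tau_rise, tau_decay = tau_decay,
                       seed = seed))
  })
}

#' Generate a synthetic respiration waveform
#'
#' Oscillatory chest-band signal built cycle by cycle, with configurable
#' inhale fraction and mild cycle-to-cycle variability.  True breath-cycle
#' onset times are returned.
#'
#' @param duration_s Duration in seconds.
#' @param breath_rate_bpm Breathing rate, 3-180 breaths per minute.
#' @param amp Breath amplitude (arbitrary units).
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param inhale_frac Fraction of each cycle spent inhaling.
#' @param cycle_cv Coefficient of variation of cycle durations.
#' @param noise_sd Additive noise SD.
#' @return List with `signal`, `fs`, `cycle_times` (s), and `params`.
#' @export
generate_resp <- function(duration_s, breath_rate_bpm = 15, amp = 1,
                          fs = 32, seed = 1, inhale_frac = 0.5,
                          cycle_cv = 0.05, noise_sd = 0.02) {
  assert_that(breath_rate_bpm >= 3 && breath_rate_bpm <= 180,
              "breath_rate_bpm must be within 3-180")
  assert_that(inhale_frac > 0 && inhale_frac < 1,
              "inhale_frac must be in (0, 1)")
  with_seed(seed, {
    mean_T <- 60 / breath_rate_bpm
    n <- round(duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    cycle_times <- numeric(0)
    phase <- numeric(n)
    cur <- 0
    while (cur < duration_s) {
      cycle_times <- c(cycle_times, cur)
      T <- mean_T * exp(rnorm(1, 0, cycle_cv))
      ti <- inhale_frac * T
      idx <- which(t >= cur & t < cur + T)
      if (length(idx)) {
        rel <- t[idx] - cur
        # phase runs 0..pi over the inhale, pi..2*pi over the exhale
        phase[idx] <- ifelse(rel < ti, pi * rel / ti,
                             pi + pi * (rel - ti) / (T - ti))
      }
      cur <- cur + T
    }
    signal <- amp * (-cos(phase)) / 2 + rnorm(n, 0, noise_sd)
    list(signal = signal, fs = fs, cycle_times = cycle_times,
         params = list(breath_rate_bpm = breath_rate_bpm, amp = amp,
                       inhale_frac = inhale_frac, seed = seed))
  })
}

eeg_default_band_targets <- function() {
  c(delta = 30, theta = 15, alpha = 20, beta = 8, gamma = 3)
}

# Frequency-domain synthesis of band-structured noise: each band has a
# 4th-order-Butterworth-magnitude envelope (equivalent to filtered white
# noise), scaled analytically so the expected band variance hits its
# target; all bands share one inverse FFT per channel.
band_gain <- function(n, fs, lo, hi) {
  f <- (1:floor(n / 2)) * fs / n
  1 / sqrt(1 + (f / hi)^8) / sqrt(1 + (lo / f)^8)
}

shaped_noise <- function(n, gain_comb) {
  nf <- length(gain_comb)
  z <- (rnorm(nf) + 1i * rnorm(nf)) * gain_comb
  spec <- complex(length.out = n)
  spec[2:(nf + 1)] <- z
  spec[n:(n - nf + 2)] <- Conj(z[1:(nf - 1)])
  Re(fft(spec, inverse = TRUE)) / n
}

# Variance of shaped_noise output given per-bin gain: each bin k contributes
# Var((2/n) Re(z_k e^{i theta})) = 4 gain_k^2 / n^2 (conjugate half folded).
shaped_noise_var <- function(n, gain) 4 * sum(gain^2) / n^2

#' Generate a synthetic multichannel EEG recording
#'
#' Each channel is a sum of band-limited noise components scaled to target
#' band powers, plus blink-artifact transients shared across channels and
#' weighted toward the frontal electrodes.  Channel labels follow the 19-lead
#' 10-20 montage.
#'
#' @param duration_s Duration in seconds.
#' @param n_channels Channel count; values other than 19 require
#'   `allow_nonstandard_channels = TRUE`.
#' @param band_power_targets Named numeric of target band variances
#'   (uV^2) for `delta`, `theta`, `alpha`, `beta`, `gamma`.
#' @param blink_rate_per_min Poisson rate of blink artifacts.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param channel_band_scale Optional named list: per-channel named numeric
#'   multipliers of band amplitude, e.g. `list(pz = c(alpha = 1.5))`.
#' @param blink_amp_uV Blink transient peak amplitude at Fp1/Fp2.
#' @param allow_nonstandard_channels Permit `n_channels != 19`.
#' @return List with `signal` (channels x samples matrix, labeled rows),
#'   `fs`, `channels`, `blink_times`, and `params`.
#' @export
generate_eeg <- function(duration_s, n_channels = 19L,
                         band_power_targets = eeg_default_band_targets(),
                         blink_rate_per_min = 12, fs = 250, seed = 1,
                         channel_band_scale = NULL, blink_amp_uV = 80,
                         allow_nonstandard_channels = FALSE) {
  assert_that(setequal(names(band_power_targets), .eeg_bands),
              "band_power_targets must be keyed by the five canonical bands")
  if (n_channels != 19L && !allow_nonstandard_channels) {
    abort("n_channels != 19 requires allow_nonstandard_channels = TRUE")
  }
  channels <- if (n_channels == 19L) .eeg_channels else
    paste0("ch", seq_len(n_channels))
  with_seed(seed, {
    n <- round(duration_s * fs)
    gains <- lapply(.eeg_bands, function(band) {
      edges <- pmin(.eeg_band_edges[[band]], 0.99 * fs / 2)
      g <- band_gain(n, fs, edges[1], edges[2])
      g / sqrt(shaped_noise_var(n, g))  # unit-variance band component
    })
    names(gains) <- .eeg_bands
    sig <- matrix(0, nrow = n_channels, ncol = n,
                  dimnames = list(channels, NULL))
    for (ci in seq_len(n_channels)) {
      cbs <- channel_band_scale[[channels[ci]]]
      g2 <- 0
      for (band in .eeg_bands) {
        scale_mult <- if (!is.null(cbs) && band %in% names(cbs))
          cbs[[band]] else 1
        target_sd <- sqrt(band_power_targets[[band]]) * scale_mult
        g2 <- g2 + (target_sd * gains[[band]])^2
      }
      sig[ci, ] <- shaped_noise(n, sqrt(g2))
    }
    n_blinks <- rpois(1, blink_rate_per_min * duration_s / 60)
    blink_times <- sort(runif(n_blinks, 0.3, max(duration_s - 0.5, 0.3)))
    if (n_blinks > 0) {
      w <- eeg_blink_weights(channels)
      dur <- 0.35
      for (bt in blink_times) {
        i0 <- floor(bt * fs) + 1L
        len <- round(dur * fs)
        idx <- i0:min(n, i0 + len - 1L)
        pulse <- blink_amp_uV * sin(pi * seq_along(idx) / len)^2
        sig[, idx] <- sig[, idx] + outer(w, pulse)
      }
    }
    list(signal = sig, fs = fs, channels = channels,
         blink_times = blink_times,
         params = list(band_power_targets = band_power_targets,
                       channel_band_scale = channel_band_scale,
                       blink_rate_per_min = blink_rate_per_min,
                       seed = seed))
  })
}

# Spatial weighting of blink artifacts: strongest at Fp1/Fp2, decaying toward
# posterior sites.
eeg_blink_weights <- function(channels) {
  w <- setNames(rep(0.02, length(channels)), channels)
  front <- c(fp1 = 1, fp2 = 1, f7 = 0.45, f3 = 0.5, fz = 0.5, f4 = 0.5,
             f8 = 0.45, c3 = 0.15, cz = 0.15, c4 = 0.15)
  hit <- intersect(names(front), channels)
  w[hit] <- front[hit]
  unname(w[channels])
}
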