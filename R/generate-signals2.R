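# Generators for fNIRS, eye tracking, embedded task measures, and operator
# background variables.

# Hemodynamic response kernel: gamma-shaped rise with a smaller, slower
# undershoot; unit peak at `peak_s`.
hrf_kernel <- function(fs, peak_s = 6, length_s = 25) {
  shape <- 6
  raw <- function(t) {
    scale1 <- peak_s / (shape - 1)
    h <- (t / scale1)^(shape - 1) * exp(-(t / scale1 - (shape - 1)))
    scale2 <- 2 * peak_s / (shape - 1)
    u <- (t / scale2)^(shape - 1) * exp(-(t / scale2 - (shape - 1)))
    h - 0.25 * u
  }
  # the undershoot pulls the composite mode below peak_s: find the true
  # mode on a fine grid and stretch the time axis so the peak lands on it
  fine <- seq(0, 2 * peak_s, by = peak_s / 500)
  p0 <- fine[which.max(raw(fine))]
  t <- seq(0, length_s, by = 1 / fs)
  k <- raw(t * p0 / peak_s)
  k / max(k)
}

#' Generate synthetic fNIRS HbO/HbR series
#'
#' Each of 20 source-detector channels carries hemodynamic-response pulses at
#' Poisson times (HbO positive, HbR a scaled negative mirror), slow linear
#' drift, cardiac ripple, and noise.  Truth parameters (event onsets, kernel
#' peak time, per-channel amplitude scale) are returned.
#'
#' @param duration_s Duration in seconds.
#' @param n_channels Channel count (20 unless overridden).
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param hrf_rate_per_min Poisson rate of hemodynamic events per channel
#'   (default 4/min, matching the task's ~2 stimuli per 30 s).
#' @param hrf_amp Typical HbO event peak amplitude (uM).
#' @param hrf_peak_s Kernel time-to-peak (s).
#' @param channel_amp_scale Optional numeric vector (length `n_channels`) of
#'   per-channel amplitude multipliers.
#' @param drift_sd Slope SD of the per-channel linear drift (uM/min).
#' @param cardiac_amp,cardiac_freq Cardiac ripple amplitude (uM) / frequency (Hz).
#' @param noise_sd Additive noise SD (uM).
#' @param hbr_ratio HbR amplitude as a (negative) fraction of HbO.
#' @param allow_nonstandard_channels Permit `n_channels != 20`.
#' @return List with `hbo`, `hbr` (channel x sample matrices), `fs`,
#'   `events` (per-channel list of onset times), and `params`.
#' @export
generate_fnirs <- function(duration_s, n_channels = 20L, fs = 10, seed = 1,
                           hrf_rate_per_min = 4, hrf_amp = 1, hrf_peak_s = 6,
                           channel_amp_scale = NULL, drift_sd = 0.3,
                           cardiac_amp = 0.08, cardiac_freq = 1.1,
                           noise_sd = 0.05, hbr_ratio = -0.4,
                           allow_nonstandard_channels = FALSE) {
  if (n_channels != 20L && !allow_nonstandard_channels) {
    abort("n_channels != 20 requires allow_nonstandard_channels = TRUE")
  }
  assert_that(hrf_rate_per_min >= 0 && hrf_amp >= 0 && hrf_peak_s > 0,
              "hrf parameters must be non-negative (peak time positive)")
  if (is.null(channel_amp_scale)) channel_amp_scale <- rep(1, n_channels)
  assert_that(length(channel_amp_scale) == n_channels,
              "channel_amp_scale must have one value per channel")
  with_seed(seed, {
    n <- round(duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    k <- hrf_kernel(fs, hrf_peak_s)
    hbo <- matrix(0, n_channels, n)
    hbr <- matrix(0, n_channels, n)
    events <- vector("list", n_channels)
    for (ci in seq_len(n_channels)) {
      n_ev <- rpois(1, hrf_rate_per_min * duration_s / 60)
      onsets <- sort(runif(n_ev, 0, max(duration_s - hrf_peak_s, 1)))
      events[[ci]] <- onsets
      resp <- numeric(n)
      for (on in onsets) {
        i0 <- floor(on * fs) + 1L
        idx <- i0:min(n, i0 + length(k) - 1L)
        resp[idx] <- resp[idx] +
          hrf_amp * channel_amp_scale[ci] * exp(rnorm(1, 0, 0.1)) *
          k[seq_along(idx)]
      }
      drift_o <- rnorm(1, 0, drift_sd) * t / 60
      drift_r <- rnorm(1, 0, drift_sd / 2) * t / 60
      card <- cardiac_amp * sin(2 * pi * cardiac_freq * t + runif(1, 0, 2 * pi))
      hbo[ci, ] <- resp + drift_o + card + rnorm(n, 0, noise_sd)
      hbr[ci, ] <- hbr_ratio * resp + drift_r + 0.5 * card +
        rnorm(n, 0, noise_sd * 0.7)
    }
    list(hbo = hbo, hbr = hbr, fs = fs, events = events,
         params = list(hrf_rate_per_min = hrf_rate_per_min,
                       hrf_amp = hrf_amp, hrf_peak_s = hrf_peak_s,
                       channel_amp_scale = channel_amp_scale,
                       hbr_ratio = hbr_ratio, seed = seed))
  })
}

#' Generate synthetic eye-tracking data
#'
#' Produces a pupil-diameter series (slow wander, hippus oscillation, blink
#' dips) plus blink, fixation, and saccade event lists over four screen areas
#' of interest.
#'
#' @param duration_s Duration in seconds.
#' @param fs Pupil sampling rate in Hz.
#' @param seed Integer seed.
#' @param pupil_mean_mm Mean pupil diameter (mm).
#' @param blink_rate_per_min Poisson blink rate.
#' @param blink_dur_s Mean blink duration (s).
#' @param fix_dur_mean_s Mean fixation duration (s).
#' @param aoi_probs Probability over the four areas of interest.
#' @param sacc_amp_mean_deg Mean saccade amplitude (degrees).
#' @return List with `pupil`, `fs`, `blinks`, `fixations`, `saccades`
#'   (tibbles), and `params`.
#' @export
generate_eye <- function(duration_s, fs = 120, seed = 1,
                         pupil_mean_mm = 3.5, blink_rate_per_min = 12,
                         blink_dur_s = 0.15, fix_dur_mean_s = 0.30,
                         aoi_probs = c(0.25, 0.25, 0.25, 0.25),
                         sacc_amp_mean_deg = 5) {
  assert_that(pupil_mean_mm > 1 && pupil_mean_mm < 9,
              "pupil_mean_mm outside physiological range")
  assert_that(length(aoi_probs) == 4L && all(aoi_probs >= 0) &&
                sum(aoi_probs) > 0, "aoi_probs must be 4 non-negative values")
  aoi_probs <- aoi_probs / sum(aoi_probs)
  with_seed(seed, {
    n <- round(duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    wander <- as.numeric(stats::filter(rnorm(n, 0, 0.02), 0.995,
                                       method = "recursive"))
    pupil <- pupil_mean_mm + wander +
      0.1 * sin(2 * pi * 0.2 * t + runif(1, 0, 2 * pi)) +
      rnorm(n, 0, 0.02)
    # blinks
    n_b <- rpois(1, blink_rate_per_min * duration_s / 60)
    b_on <- sort(runif(n_b, 0, max(duration_s - 0.5, 0.1)))
    b_dur <- pmax(0.06, rnorm(n_b, blink_dur_s, 0.04))
    for (i in seq_len(n_b)) {
      idx <- which(t >= b_on[i] & t < b_on[i] + b_dur[i])
      if (length(idx)) {
        pupil[idx] <- pupil[idx] -
          1.5 * sin(pi * seq_along(idx) / length(idx))
      }
    }
    blinks <- tibble(onset = b_on, duration = b_dur)
    # fixation/saccade alternation
    fix_on <- numeric(0); fix_dur <- numeric(0); fix_aoi <- integer(0)
    sac_on <- numeric(0); sac_dur <- numeric(0); sac_amp <- numeric(0)
    cur <- runif(1, 0, 0.1)
    while (cur < duration_s) {
      d <- stats::rlnorm(1, log(fix_dur_mean_s) - 0.08, 0.4)
      if (cur + d > duration_s) break
      fix_on <- c(fix_on, cur)
      fix_dur <- c(fix_dur, d)
      fix_aoi <- c(fix_aoi, sample.int(4L, 1L, prob = aoi_probs))
      cur <- cur + d
      sd_ <- runif(1, 0.02, 0.06)
      if (cur + sd_ > duration_s) break
      sac_on <- c(sac_on, cur)
      sac_dur <- c(sac_dur, sd_)
      sac_amp <- c(sac_amp, stats::rgamma(1, shape = 4,
                                          scale = sacc_amp_mean_deg / 4))
      cur <- cur + sd_
    }
    list(
      pupil = pupil, fs = fs, blinks = blinks,
      fixations = tibble(onset = fix_on, duration = fix_dur, aoi = fix_aoi),
      saccades = tibble(onset = sac_on, duration = sac_dur,
                        amplitude = sac_amp),
      params = list(pupil_mean_mm = pupil_mean_mm,
                    blink_rate_per_min = blink_rate_per_min,
                    fix_dur_mean_s = fix_dur_mean_s,
                    aoi_probs = aoi_probs, seed = seed)
    )
  })
}

# Behavioral noise scale of the embedded-measure links (SD of the latent
# uniform-ish propensities behind counts/percentages).  Chosen so each
# behavioral measure correlates with trust at roughly r ~ 0.2-0.3: strong
# enough to be informative and retained by selection, weak enough that the
# behavioral block does not collectively screen off the physiological
# signal.
embedded_link_noise <- function() 0.45

#' Generate embedded task-interaction measures for one trial
#'
#' Maps the trial's per-epoch trust values through monotone behavioral links
#' with noise: a trusting operator reviews fewer classifications, agrees
#' (often passively) more, decides faster, and spends more effort on the map
#' task.  Three satellite classifications and three allowed map interactions
#' arrive per 45-s epoch.
#'
#' @param trust Numeric vector of the trial's per-epoch trust values in
#'   `[0, 1]`.
#' @param session,trial Indices recorded as embedded measures.
#' @param explainability `"low"` or `"high"` (session condition).
#' @param seed Integer seed.
#' @param link_noise Behavioral noise SD on the latent propensities.
#' @return Tibble with one row per epoch and the 16 embedded-measure columns.
#' @export
generate_embedded <- function(trust, session, trial, explainability,
                              seed = 1, link_noise = embedded_link_noise()) {
  n_ep <- length(trust)
  n_sat <- 3L   # classifications per epoch
  n_map <- 3L   # allowed map interactions per epoch
  with_seed(seed, {
    p_review <- clamp(0.85 - 0.6 * trust + rnorm(n_ep, 0, link_noise), 0.02, 0.98)
    n_reviewed <- rbinom(n_ep, n_sat, p_review)
    per_sat_time <- clamp(6 * (1 - trust) + 1.5 + rnorm(n_ep, 0, 8 * link_noise),
                          0.5, 20)
    pct_agree <- clamp(50 + 45 * (trust - 0.5) / 0.5 +
                         rnorm(n_ep, 0, 100 * link_noise), 0, 100)
    pct_passive <- clamp(15 + 75 * trust + rnorm(n_ep, 0, 100 * link_noise),
                         0, 100)
    latency <- clamp(5 * (1 - trust) + 1 + rnorm(n_ep, 0, 6 * link_noise),
                     0.3, 20)
    pct_rereview <- clamp(30 * (1 - trust) + rnorm(n_ep, 0, 60 * link_noise),
                          0, 100)
    p_map <- clamp(0.25 + 0.55 * trust + rnorm(n_ep, 0, link_noise), 0.02, 0.98)
    n_map_sel <- rbinom(n_ep, n_map, p_map)
    switches <- rpois(n_ep, pmax(0.3, 6 * (1 - trust) + 1))
    reliance <- clamp(mean(trust) + rnorm(1, 0, 0.1), 0, 1)
    tibble(
      emb_session = as.numeric(session),
      emb_trial = as.numeric(trial),
      emb_epoch = as.numeric(seq_len(n_ep)),
      emb_review_time_total = n_reviewed * per_sat_time,
      emb_review_time_avg = ifelse(n_reviewed > 0, per_sat_time, 0),
      emb_pct_reviewed = 100 * n_reviewed / n_sat,
      emb_pct_ignored = 100 * (1 - n_reviewed / n_sat),
      emb_pct_agreement = pct_agree,
      emb_pct_passive_agreement = pct_passive,
      emb_decision_latency = latency,
      emb_pct_rereviewed = pct_rereview,
      emb_map_selections = as.numeric(n_map_sel),
      emb_pct_map_interactions = 100 * n_map_sel / n_map,
      emb_reliance_slider = rep(reliance, n_ep),
      emb_screen_switches = as.numeric(switches),
      emb_explainability = as.numeric(explainability == "high")
    )
  })
}

#' Generate operator background variables
#'
#' One row per participant: eight pre-experiment survey subscale scores
#' (1-7 Likert means), ten demographic/experience items (numeric-coded),
#' self-reported sleep hours, and six psychomotor-vigilance summary metrics
#' (ms / counts).
#'
#' @param n_participants Number of participants.
#' @param seed Integer seed.
#' @return List with `background` (tibble, `participant` + 25 columns) and
#'   `propensity_z` (standardized propensity-to-trust scores, used by the
#'   study generator for the dispositional trust shift).
#' @export
generate_background <- function(n_participants, seed = 1) {
  with_seed(seed, {
    lik <- function(mu, s = 0.8) clamp(rnorm(n_participants, mu, s), 1, 7)
    pt_raw <- lik(4.4)
    rt_mean <- rnorm(n_participants, 320, 30)
    bg <- tibble(
      participant = seq_len(n_participants),
      bg_big5_extraversion = lik(4.1),
      bg_big5_agreeableness = lik(5.0),
      bg_pas_high_expectations = lik(4.6),
      bg_cvs_masculinity = lik(3.4),
      bg_propensity_to_trust = pt_raw,
      bg_aicp = lik(3.9),
      bg_utaut_performance = lik(4.8),
      bg_utaut_effort = lik(4.9),
      bg_age = round(clamp(rnorm(n_participants, 26, 8), 18, 65)),
      bg_sex = rbinom(n_participants, 1, 0.45),
      bg_race = sample(1:5, n_participants, replace = TRUE),
      bg_ethnicity = rbinom(n_participants, 1, 0.2),
      bg_dominant_hand = rbinom(n_participants, 1, 0.9),
      bg_videogame_exp = sample(1:5, n_participants, replace = TRUE),
      bg_robotics_exp = sample(1:5, n_participants, replace = TRUE),
      bg_navaid_use = sample(1:5, n_participants, replace = TRUE),
      bg_aerospace_display_exp = sample(1:5, n_participants, replace = TRUE),
      bg_military_monitoring_exp = sample(1:5, n_participants, replace = TRUE),
      bg_sleep_hours = clamp(rnorm(n_participants, 7.2, 1), 4, 10),
      bg_pvt_rt_mean = rt_mean,
      bg_pvt_rt_median = rt_mean - abs(rnorm(n_participants, 10, 5)),
      bg_pvt_rt_sd = abs(rnorm(n_participants, 55, 12)),
      bg_pvt_lapses = rpois(n_participants, 2),
      bg_pvt_false_starts = rpois(n_participants, 1),
      bg_pvt_rt_fastest10 = rt_mean - abs(rnorm(n_participants, 70, 15))
    )
    pz <- as.numeric(scale(pt_raw))
    if (any(!is.finite(pz))) pz <- rep(0, n_participants)
    list(background = bg, propensity_z = pz)
  })
}
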