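# The study generator: protocol hierarchy, planted sparse trust structure,
# per-epoch generator parameters, and deterministic lazy signal bundles.

# Default (resting / z = 0) generator parameters for one epoch.
default_epoch_params <- function() {
  tibble(
    hr_bpm = 70, hrv_sd_ms = 40,
    tonic_uS = 8, tonic_slope_uS_min = 0, scr_amp_uS = 0.5,
    scr_rate_per_min = 4,
    breath_rate_bpm = 15, rsp_amp = 1, inhale_frac = 0.5,
    alpha_pz = 1, theta_fz = 1, alpha_o1 = 1,
    fnirs_amp_ch01 = 1, fnirs_amp_ch05 = 1,
    pupil_mean_mm = 3.5, blink_rate_per_min = 12, fix_dur_mean_s = 0.30
  )
}

# Monotone links from planted latent z-scores to generator parameters.
# Applied on top of the resting defaults; features not planted keep z = 0.
apply_latent_links <- function(params, z) {
  g <- function(f) if (f %in% colnames(z)) z[, f] else 0
  params$hr_bpm <- 70 * exp(-0.08 * g("ecg_rr_mean"))
  params$hrv_sd_ms <- 40 * exp(0.35 * g("ecg_sdnn"))
  params$tonic_uS <- clamp(8 + 1.2 * g("eda_scl_mean"), 1.5, 39)
  params$tonic_slope_uS_min <- 1.2 * g("eda_scl_slope")
  params$scr_amp_uS <- 0.5 * exp(0.5 * g("eda_scr_amp_mean"))
  params$breath_rate_bpm <- clamp(15 + 1.8 * g("rsp_breath_rate"), 6, 30)
  params$rsp_amp <- exp(0.25 * g("rsp_amp_mean"))
  params$alpha_pz <- exp(0.4 * g("eeg_pz_alpha"))
  params$theta_fz <- exp(0.4 * g("eeg_fz_theta"))
  params$alpha_o1 <- exp(0.4 * g("eeg_o1_alpha"))
  params$fnirs_amp_ch01 <- exp(0.6 * g("fnirs_ch01_hbo_max"))
  params$fnirs_amp_ch05 <- exp(0.6 * g("fnirs_ch05_hbo_max"))
  params$pupil_mean_mm <- clamp(3.5 + 0.35 * g("eye_pupil_mean"), 2, 6)
  params$blink_rate_per_min <- 12 * exp(0.5 * g("eye_blink_rate"))
  params$fix_dur_mean_s <- 0.30 * exp(0.25 * g("eye_fix_dur_mean"))
  params
}

#' Generate a synthetic trust study
#'
#' Builds a full dataset with the protocol hierarchy of the emulated study:
#' per-epoch latent physiological states drive stream generator parameters,
#' trust is a planted sparse linear function of those states (plus session
#' condition, participant disposition, and noise, clipped to `[0, 1]`),
#' embedded behavioral measures are generated from trust, and operator
#' background variables are drawn per participant.
#'
#' Raw signal bundles are not held in memory: every trial and baseline
#' window has a named child seed recorded in the dataset, and
#' [epoch_signals()] / [baseline_signals()] regenerate the corresponding
#' waveforms deterministically on demand.
#'
#' @param design A [study_design()].
#' @param spec A [trust_spec()].
#' @param seed Integer master seed.
#' @return An object of class `trust_study`: a list with `design`, `spec`,
#'   `index` (tibble: keys, condition, trust `y`, per-stream missingness
#'   flags), `embedded`, `background`, `truth` (planted coefficients, latent
#'   `z` scores, pre-clipping trust, participant shifts), and `seed`.
#' @examples
#' study <- generate_study(study_design(n_participants = 1, n_sessions = 1,
#'                                      n_trials = 1, n_epochs = 8), seed = 1)
#' nrow(study$index)
#' @export
generate_study <- function(design = study_design(), spec = trust_spec(),
                           seed = 1L) {
  stopifnot(inherits(design, "study_design"), inherits(spec, "trust_spec"))
  index <- tidyr::expand_grid(
    participant = seq_len(design$n_participants),
    session = seq_len(design$n_sessions),
    trial = seq_len(design$n_trials),
    epoch = seq_len(design$n_epochs)
  )
  n <- nrow(index)

  # session -> condition assignment, randomized per participant
  cond <- with_seed(child_seed(seed, "cond"), {
    purrr::map(seq_len(design$n_participants), function(p) {
      tibble(participant = p, session = seq_len(design$n_sessions),
             condition = sample(rep_len(1:4, design$n_sessions)))
    })
  })
  cond <- purrr::list_rbind(cond) |> left_join(condition_grid(), by = "condition")
  index <- left_join(index, cond, by = c("participant", "session"))

  # latent z-scores per epoch: a shared arousal factor plus unique parts
  k <- length(spec$active_features)
  rho <- spec$latent_correlation %||% 0
  z <- with_seed(child_seed(seed, "z"), {
    g <- rnorm(n)
    e <- matrix(rnorm(n * k), n, k)
    sqrt(rho) * g + sqrt(1 - rho) * e
  })
  dimnames(z) <- list(NULL, spec$active_features)

  bg <- generate_background(design$n_participants,
                            seed = child_seed(seed, "bg"))
  w <- spec$dispositional_weight
  pshift <- with_seed(child_seed(seed, "pshift"), {
    spec$participant_sd *
      (w * bg$propensity_z +
         sqrt(max(0, 1 - w^2)) * rnorm(design$n_participants))
  })

  cond_shift <- spec$condition_effects[["reliability_high"]] *
    (index$reliability > 0.75) +
    spec$condition_effects[["explainability_high"]] *
    (index$explainability == "high")
  cond_shift <- cond_shift - mean(cond_shift)

  eps <- with_seed(child_seed(seed, "noise"), rnorm(n, 0, spec$noise_sd))
  trust_state <- spec$intercept + cond_shift + pshift[index$participant] +
    as.numeric(z %*% spec$coefficients)
  latent <- trust_state + eps
  index$y <- clamp(latent, 0, 1)
  for (s in stream_names()) index[[paste0("miss_", s)]] <- FALSE

  # per-epoch generator parameters
  params <- apply_latent_links(
    default_epoch_params()[rep(1L, n), ], z
  )

  # embedded measures, one generator call per trial, driven by the
  # operator's noise-free trust state (behavior reflects internal trust,
  # not the slider's report noise); the reliance slider is a post-trial
  # report broadcast to its epochs
  trust_for_links <- clamp(trust_state, 0, 1)
  trials <- distinct(index, .data$participant, .data$session, .data$trial,
                     .data$explainability)
  emb <- purrr::pmap(trials, function(participant, session, trial,
                                      explainability) {
    sel <- index$participant == participant & index$session == session &
      index$trial == trial
    generate_embedded(trust_for_links[sel], session, trial, explainability,
                      seed = child_seed(seed, "emb", participant, session,
                                        trial))
  })
  embedded <- bind_cols(
    select(index, "participant", "session", "trial", "epoch"),
    purrr::list_rbind(emb)
  )

  structure(
    list(
      design = design, spec = spec, seed = as.integer(seed),
      index = index,
      embedded = embedded,
      background = bg$background,
      truth = list(
        active_features = spec$active_features,
        coefficients = spec$coefficients,
        intercept = spec$intercept,
        noise_sd = spec$noise_sd,
        z = z,
        latent_trust = latent,
        participant_shift = pshift,
        params = params
      )
    ),
    class = "trust_study"
  )
}

#' @export
print.trust_study <- function(x, ...) {
  d <- x$design
  cat("<trust_study> ", nrow(x$index), " epochs (",
      d$n_participants, "x", d$n_sessions, "x", d$n_trials, "x", d$n_epochs,
      "), seed ", x$seed, "\n", sep = "")
  n_miss <- sum(as.matrix(select(x$index, starts_with("miss_"))))
  cat("  planted features: ", length(x$spec$active_features),
      "; flagged stream-epochs: ", n_miss, "\n", sep = "")
  invisible(x)
}

stream_names <- function() c("ecg", "eda", "rsp", "eeg", "fnirs", "eye")

# Trial-level EDA: the tonic level must be continuous across epoch
# boundaries (a level step would deconvolve into a spurious SCR-like driver
# spike), so the tonic path interpolates linearly through two anchors per
# epoch that encode the epoch's planted level and slope; SCR amplitudes
# follow the epoch containing each event.
eda_trial_signals <- function(study, participant, session, trial) {
  d <- study$design
  fs <- d$fs$eda
  idx <- study$index
  sel <- which(idx$participant == participant & idx$session == session &
                 idx$trial == trial)
  sel <- sel[order(idx$epoch[sel])]
  pr <- study$truth$params[sel, ]
  n_ep <- length(sel)
  ep_s <- d$epoch_s
  dur <- n_ep * ep_s
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  seed <- child_seed(study$seed, "sig", participant, session, trial,
                     "eda_trial")
  with_seed(seed, {
    anchors_t <- as.vector(vapply(seq_len(n_ep), function(e)
      (e - 1) * ep_s + c(0.25, 0.75) * ep_s, numeric(2)))
    anchors_v <- as.vector(vapply(seq_len(n_ep), function(e) {
      dv <- pr$tonic_slope_uS_min[e] * (0.25 * ep_s) / 60
      pr$tonic_uS[e] + c(-dv, dv)
    }, numeric(2)))
    tonic <- approx(anchors_t, anchors_v, xout = t, rule = 2)$y +
      0.15 * sin(2 * pi * t / 90 + runif(1, 0, 2 * pi))
    rate <- pr$scr_rate_per_min[1]
    n_scr <- rpois(1, rate * dur / 60)
    signal <- tonic
    if (n_scr > 0) {
      times <- sort(runif(n_scr, 0, dur - 3))
      ep_of <- pmin(floor(times / ep_s) + 1L, n_ep)
      amps <- pr$scr_amp_uS[ep_of] * exp(rnorm(n_scr, 0, 0.2))
      k <- bateman_kernel(fs)
      for (i in seq_len(n_scr)) {
        i0 <- floor(times[i] * fs) + 1L
        ii <- i0:min(n, i0 + length(k) - 1L)
        signal[ii] <- signal[ii] + amps[i] * k[seq_along(ii)]
      }
      events <- tibble(time = times, amplitude = amps)
    } else {
      events <- tibble(time = numeric(), amplitude = numeric())
    }
    signal <- signal + rnorm(n, 0, 0.01)
    list(signal = signal, fs = fs, tonic = tonic, scr_events = events,
         params = list(seed = seed))
  })
}

# Generate the raw signal bundle for one epoch (deterministic in the study
# seed).  `params_row` overrides lookup, used for baseline windows.
build_epoch_bundle <- function(study, duration_s, params_row, seed_key) {
  d <- study$design
  fs <- d$fs
  p <- params_row
  list(
    ecg = generate_ecg(duration_s, mean_hr_bpm = p$hr_bpm,
                       hrv_sd_ms = p$hrv_sd_ms, fs = fs$ecg,
                       seed = child_seed(study$seed, seed_key, "ecg")),
    eda = generate_eda(duration_s, tonic_level_uS = clamp(p$tonic_uS, 1, 40),
                       scr_rate_per_min = p$scr_rate_per_min,
                       scr_amp_uS = p$scr_amp_uS, fs = fs$eda,
                       drift_slope_uS_min = p$tonic_slope_uS_min,
                       seed = child_seed(study$seed, seed_key, "eda")),
    rsp = generate_resp(duration_s, breath_rate_bpm = p$breath_rate_bpm,
                        amp = p$rsp_amp, inhale_frac = p$inhale_frac,
                        fs = fs$rsp,
                        seed = child_seed(study$seed, seed_key, "rsp")),
    eeg = generate_eeg(duration_s, fs = fs$eeg,
                       channel_band_scale = list(
                         pz = c(alpha = p$alpha_pz),
                         fz = c(theta = p$theta_fz),
                         o1 = c(alpha = p$alpha_o1)),
                       seed = child_seed(study$seed, seed_key, "eeg")),
    fnirs = generate_fnirs(duration_s, fs = fs$fnirs,
                           channel_amp_scale = {
                             sc <- rep(1, 20)
                             sc[1] <- p$fnirs_amp_ch01
                             sc[5] <- p$fnirs_amp_ch05
                             sc
                           },
                           seed = child_seed(study$seed, seed_key, "fnirs")),
    eye = generate_eye(duration_s, fs = fs$pupil,
                       pupil_mean_mm = p$pupil_mean_mm,
                       blink_rate_per_min = p$blink_rate_per_min,
                       fix_dur_mean_s = p$fix_dur_mean_s,
                       seed = child_seed(study$seed, seed_key, "eye"))
  )
}

#' Materialize the raw signals of one epoch
#'
#' Regenerates the epoch's six-stream signal bundle deterministically from
#' the study's seed tree and that epoch's generator parameters.
#'
#' @param study A [generate_study()] result.
#' @param participant,session,trial,epoch 1-based indices.
#' @return Named list of generator outputs
#'   (`ecg`, `eda`, `rsp`, `eeg`, `fnirs`, `eye`).
#' @export
epoch_signals <- function(study, participant, session, trial, epoch) {
  stopifnot(inherits(study, "trust_study"))
  sel <- which(study$index$participant == participant &
                 study$index$session == session &
                 study$index$trial == trial &
                 study$index$epoch == epoch)
  assert_that(length(sel) == 1L, "epoch not found in study index")
  bundle <- build_epoch_bundle(study, study$design$epoch_s,
                               study$truth$params[sel, ],
                               seed_key = paste("sig", participant, session,
                                                trial, epoch, sep = "/"))
  # EDA comes from the continuous trial-level signal, sliced to this epoch
  tr <- eda_trial_signals(study, participant, session, trial)
  ep_s <- study$design$epoch_s
  t0 <- (epoch - 1) * ep_s
  ii <- (round(t0 * tr$fs) + 1L):round((t0 + ep_s) * tr$fs)
  bundle$eda <- list(
    signal = tr$signal[ii], fs = tr$fs, tonic = tr$tonic[ii],
    scr_events = tr$scr_events |>
      filter(.data$time >= t0, .data$time < t0 + ep_s) |>
      mutate(time = .data$time - t0),
    params = tr$params
  )
  bundle
}

#' Materialize a baseline window
#'
#' Pre-trial baselines for trials 2+ are their own 45-s rest windows; trial 1
#' has no separate pre-trial baseline (the first trial starts right after the
#' pre-experimental rest), so its window is the tail of the pre-experimental
#' baseline.  With `trial = NULL` the full pre-experimental baseline is
#' returned.
#'
#' @inheritParams epoch_signals
#' @param trial Trial whose pre-trial baseline is wanted, or `NULL` for the
#'   session's pre-experimental baseline.
#' @return Named list of generator outputs at resting parameters.
#' @export
baseline_signals <- function(study, participant, session, trial = NULL) {
  stopifnot(inherits(study, "trust_study"))
  d <- study$design
  rest <- default_epoch_params()
  if (is.null(trial) || trial == 1L) {
    bundle <- build_epoch_bundle(study, d$preexp_baseline_s, rest,
                                 seed_key = paste("preexp", participant,
                                                  session, sep = "/"))
    if (is.null(trial)) return(bundle)
    return(slice_bundle_tail(bundle, d$pretrial_baseline_s))
  }
  build_epoch_bundle(study, d$pretrial_baseline_s, rest,
                     seed_key = paste("pretrial", participant, session,
                                      trial, sep = "/"))
}

# Keep only the final `dur_s` seconds of every stream in a bundle.
slice_bundle_tail <- function(bundle, dur_s) {
  out <- bundle
  for (s in c("ecg", "eda", "rsp")) {
    x <- bundle[[s]]
    n <- length(x$signal)
    keep <- (n - round(dur_s * x$fs) + 1L):n
    t0 <- (keep[1] - 1L) / x$fs
    x$signal <- x$signal[keep]
    if (s == "ecg") {
      sel <- x$r_times >= t0
      x$r_times <- x$r_times[sel] - t0
      x$rr_s <- x$rr_s[sel]
    }
    if (s == "eda") {
      x$tonic <- x$tonic[keep]
      x$scr_events <- filter(x$scr_events, .data$time >= t0) |>
        mutate(time = .data$time - t0)
    }
    if (s == "rsp") x$cycle_times <- x$cycle_times[x$cycle_times >= t0] - t0
    out[[s]] <- x
  }
  x <- bundle$eeg
  n <- ncol(x$signal)
  keep <- (n - round(dur_s * x$fs) + 1L):n
  t0 <- (keep[1] - 1L) / x$fs
  x$signal <- x$signal[, keep, drop = FALSE]
  x$blink_times <- x$blink_times[x$blink_times >= t0] - t0
  out$eeg <- x
  x <- bundle$fnirs
  n <- ncol(x$hbo)
  keep <- (n - round(dur_s * x$fs) + 1L):n
  t0 <- (keep[1] - 1L) / x$fs
  x$hbo <- x$hbo[, keep, drop = FALSE]
  x$hbr <- x$hbr[, keep, drop = FALSE]
  out$fnirs <- x
  x <- bundle$eye
  n <- length(x$pupil)
  keep <- (n - round(dur_s * x$fs) + 1L):n
  t0 <- (keep[1] - 1L) / x$fs
  x$pupil <- x$pupil[keep]
  x$blinks <- filter(x$blinks, .data$onset >= t0) |>
    mutate(onset = .data$onset - t0)
  x$fixations <- filter(x$fixations, .data$onset >= t0) |>
    mutate(onset = .data$onset - t0)
  x$saccades <- filter(x$saccades, .data$onset >= t0) |>
    mutate(onset = .data$onset - t0)
  out$eye <- x
  out
}

#' Inject missingness into a study
#'
#' Flags individual stream-epochs, whole stream-trials, and (optionally)
#' whole stream-sessions as missing.  Trust reports are never dropped.  The
#' defaults target an overall imputed fraction of about 0.24% of stream-epoch
#' cells.
#'
#' @param study A `trust_study`.
#' @param epoch_drop_p Per stream-epoch drop probability.
#' @param trial_drop_p Per stream-trial drop probability (drops all its
#'   epochs).
#' @param session_stream_drop_count Number of whole participant-session
#'   stream losses to plant.
#' @param seed Integer seed.
#' @return The study with updated `miss_*` flags in `$index`.
#' @export
inject_missingness <- function(study, epoch_drop_p = 0.002,
                               trial_drop_p = 0.0004,
                               session_stream_drop_count = 0L,
                               seed = study$seed) {
  stopifnot(inherits(study, "trust_study"))
  assert_that(epoch_drop_p >= 0 && epoch_drop_p <= 1 &&
                trial_drop_p >= 0 && trial_drop_p <= 1,
              "drop probabilities must lie in [0, 1]")
  idx <- study$index
  d <- study$design
  streams <- stream_names()
  with_seed(child_seed(seed, "miss"), {
    for (s in streams) {
      col <- paste0("miss_", s)
      idx[[col]] <- idx[[col]] | (runif(nrow(idx)) < epoch_drop_p)
      trials <- distinct(idx, .data$participant, .data$session, .data$trial)
      hit <- runif(nrow(trials)) < trial_drop_p
      if (any(hit)) {
        bad <- trials[hit, ]
        key <- paste(idx$participant, idx$session, idx$trial)
        idx[[col]] <- idx[[col]] |
          key %in% paste(bad$participant, bad$session, bad$trial)
      }
    }
    if (session_stream_drop_count > 0) {
      sess <- distinct(idx, .data$participant, .data$session)
      pick <- sess[sample.int(nrow(sess), session_stream_drop_count,
                              replace = FALSE), ]
      pick$stream <- sample(streams, session_stream_drop_count,
                            replace = TRUE)
      for (i in seq_len(nrow(pick))) {
        col <- paste0("miss_", pick$stream[i])
        sel <- idx$participant == pick$participant[i] &
          idx$session == pick$session[i]
        idx[[col]][sel] <- TRUE
      }
    }
  })
  # a participant-session with every stream of every trial missing cannot be
  # imputed from within the session hierarchy's lower levels
  per_sess <- idx |>
    group_by(.data$participant, .data$session) |>
    summarise(all_gone = all(if_all(starts_with("miss_"), identity)),
              .groups = "drop")
  assert_that(!any(per_sess$all_gone),
              "missingness would drop every stream of an entire participant-session")
  study$index <- idx
  study
}
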