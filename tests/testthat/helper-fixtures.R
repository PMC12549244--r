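# Shared fixtures, built once per test run.  The small study uses reduced
# sampling rates (problem-size scaling for the suite; the generator's
# defaults are exercised by dedicated tests).

fixtures <- new.env(parent = emptyenv())

reduced_rates <- function() {
  list(ecg = 250, eda = 32, rsp = 32, eeg = 125, fnirs = 10, pupil = 60)
}

small_design <- function() {
  study_design(n_participants = 2, n_sessions = 2, n_trials = 3,
               n_epochs = 4, fs = reduced_rates())
}

small_study <- function() {
  if (is.null(fixtures$study)) {
    fixtures$study <- generate_study(small_design(), seed = 11)
  }
  fixtures$study
}

small_feats <- function() {
  if (is.null(fixtures$feats)) {
    fixtures$feats <- extract_features(small_study())
  }
  fixtures$feats
}

small_matrix <- function() {
  if (is.null(fixtures$fm)) {
    fixtures$fm <- impute_missing(build_design_matrix(small_feats()))
  }
  fixtures$fm
}

small_mccv <- function() {
  if (is.null(fixtures$mccv)) {
    cfg <- selection_config(n_reps_round1 = 2, n_reps_round2 = 2,
                            nlambda = 30, seed = 3)
    # the tiny fixture has far fewer epochs than the full protocol, so the
    # full-scale anti-overfitting constraints are lifted to exercise the
    # harness mechanics (the constraints have their own dedicated tests)
    fixtures$mccv <- run_mccv(small_feats(), cfg, n_splits = 2, seed = 21,
                              max_p_fraction = 1, q2_tolerance = Inf)
  }
  fixtures$mccv
}

# Build a trust_matrix by hand for imputation unit tests.
manual_matrix <- function(keys, X, y = rep(0.5, nrow(keys))) {
  structure(
    list(X = dplyr::bind_cols(keys, tibble::as_tibble(X)), y = y,
         mask = is.na(X), imputed = NULL, columns = NULL, index = keys),
    class = "trust_matrix"
  )
}
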