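# Serialization: study directories (delimited tables + JSON manifest with
# seeds and truth; waveforms are regenerable from the manifest), design
# matrices as delimited tables, and fitted models as flat text artifacts.

#' Write a study dataset to a directory
#'
#' Emits `index.tsv` (keys, condition, trust, missingness flags),
#' `embedded.tsv`, `background.tsv`, and `manifest.json` (design, trust
#' spec, master seed, planted truth).  Raw waveforms are not materialized:
#' they regenerate deterministically from the manifest seeds via
#' [epoch_signals()] after [read_study()].
#'
#' @param study A `trust_study`.
#' @param dir Output directory.
#' @param force Overwrite an existing dataset directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, force = FALSE) {
  stopifnot(inherits(study, "trust_study"))
  if (dir.exists(dir) && file.exists(file.path(dir, "manifest.json")) &&
      !force) {
    abort(paste0("'", dir, "' already holds a dataset; use force = TRUE"))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(study$index, file.path(dir, "index.tsv"))
  readr::write_tsv(study$embedded, file.path(dir, "embedded.tsv"))
  readr::write_tsv(study$background, file.path(dir, "background.tsv"))
  spec_block <- unclass(study$spec)
  # named numeric vectors lose their names as JSON arrays; store as objects
  spec_block$coefficients <- as.list(spec_block$coefficients)
  spec_block$condition_effects <- as.list(spec_block$condition_effects)
  manifest <- list(
    design = unclass(study$design),
    spec = spec_block,
    seed = study$seed,
    truth = list(
      active_features = study$truth$active_features,
      coefficients = as.list(study$truth$coefficients),
      intercept = study$truth$intercept,
      noise_sd = study$truth$noise_sd,
      participant_shift = study$truth$participant_shift
    )
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a study dataset written by [write_study()]
#'
#' Rebuilds the `trust_study` object (including regenerable signal seeds)
#' from the directory's manifest and tables.
#'
#' @param dir Dataset directory.
#' @return A `trust_study`.
#' @export
read_study <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  design <- study_design(
    n_participants = mf$design$n_participants,
    n_sessions = mf$design$n_sessions,
    n_trials = mf$design$n_trials,
    n_epochs = mf$design$n_epochs,
    epoch_s = mf$design$epoch_s,
    pretrial_baseline_s = mf$design$pretrial_baseline_s,
    preexp_baseline_s = mf$design$preexp_baseline_s,
    fs = as.list(mf$design$fs)
  )
  spec <- trust_spec(
    active_features = mf$spec$active_features,
    coefficients = unlist(mf$spec$coefficients),
    intercept = mf$spec$intercept,
    noise_sd = mf$spec$noise_sd,
    latent_correlation = mf$spec$latent_correlation %||% 0,
    condition_effects = unlist(mf$spec$condition_effects),
    participant_sd = mf$spec$participant_sd,
    dispositional_weight = mf$spec$dispositional_weight
  )
  study <- generate_study(design, spec, seed = mf$seed)
  # stored tables are authoritative (missingness flags may differ)
  study$index <- readr::read_tsv(file.path(dir, "index.tsv"),
                                 show_col_types = FALSE)
  study$embedded <- readr::read_tsv(file.path(dir, "embedded.tsv"),
                                    show_col_types = FALSE)
  study$background <- readr::read_tsv(file.path(dir, "background.tsv"),
                                      show_col_types = FALSE)
  study
}

#' Write extracted features / a design matrix as delimited tables
#'
#' @param feats A `trust_features` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_features <- function(feats, dir) {
  stopifnot(inherits(feats, "trust_features"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(feats$features, file.path(dir, "features.tsv"))
  readr::write_tsv(feats$pretrial, file.path(dir, "baseline_pretrial.tsv"))
  readr::write_tsv(feats$preexp, file.path(dir, "baseline_preexp.tsv"))
  readr::write_tsv(feats$index, file.path(dir, "epoch_index.tsv"))
  invisible(dir)
}

#' Read features written by [write_features()]
#'
#' @param dir Feature directory.
#' @param design The matching [study_design()].
#' @return A `trust_features` object.
#' @export
read_features <- function(dir, design = study_design()) {
  structure(
    list(
      features = readr::read_tsv(file.path(dir, "features.tsv"),
                                 show_col_types = FALSE),
      pretrial = readr::read_tsv(file.path(dir, "baseline_pretrial.tsv"),
                                 show_col_types = FALSE),
      preexp = readr::read_tsv(file.path(dir, "baseline_preexp.tsv"),
                               show_col_types = FALSE),
      index = readr::read_tsv(file.path(dir, "epoch_index.tsv"),
                              show_col_types = FALSE),
      design = design,
      dict = feature_dictionary()
    ),
    class = "trust_features"
  )
}

#' Write a fitted trust model as a flat text artifact
#'
#' Predictor names, coefficients, intercept, and fit statistics — enough to
#' re-score any design matrix with [read_model()] + [predict_trust()].
#'
#' @param model A `trust_model`.
#' @param path Output file (JSON).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "trust_model"))
  jsonlite::write_json(
    list(coefficients = as.list(model$coefficients),
         predictors = model$predictors,
         n = model$n, p = model$p, r2 = model$r2, adj_r2 = model$adj_r2,
         sigma = model$sigma, loto_q2 = model$loto_q2),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path Model artifact file.
#' @return A `trust_model` (without fitted values).
#' @export
read_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coefficients = unlist(m$coefficients),
                 predictors = as.character(m$predictors),
                 n = m$n, p = m$p, r2 = m$r2, adj_r2 = m$adj_r2,
                 sigma = m$sigma, fitted = NULL,
                 loto_q2 = m$loto_q2 %||% NA_real_),
            class = "trust_model")
}
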