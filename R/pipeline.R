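# Run-level drivers: each reads one config list (YAML-serializable),
# writes a versioned run directory containing the exact config used, and
# is reproducible from that directory alone.

#' Extract features and labels for a whole cohort
#'
#' @param cohort Tibble `subject, session, session_obj` (e.g. from
#'   [make_cohort()] or built from [read_session()] calls); sessions must
#'   carry hypnograms if labels are needed downstream.
#' @param config A [feature_config()].
#' @param verbose Print progress.
#' @return Tibble `subject, session, features, labels` ready for
#'   [loso_train_eval()]; `labels` is NULL-free only for labelled
#'   sessions.
#' @export
cohort_features <- function(cohort, config = feature_config(), verbose = FALSE) {
  stopifnot(all(c("subject", "session", "session_obj") %in% names(cohort)))
  rows <- map(seq_len(nrow(cohort)), function(i) {
    ses <- cohort$session_obj[[i]]
    if (verbose) message(sprintf("features: %s/%s", ses$subject_id, ses$session_id))
    fm <- assemble_features(ses, config)
    lab <- if (!is.null(ses$hypnogram)) ses$hypnogram$stage[seq_len(nrow(fm))] else NULL
    tibble(subject = cohort$subject[i], session = cohort$session[i],
           features = list(fm), labels = list(lab))
  })
  bind_rows(rows)
}

write_run_config <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(dir, "config_used.yaml"))
}

#' Generate synthetic sessions to disk
#'
#' Writes one directory per session (beats/vitals/hypnogram CSV, WAV
#' audio, YAML manifest) so the file-based pipeline can be exercised end
#' to end.
#'
#' @param config List with optional `n_subjects`, `sessions_each`,
#'   `seed`, `synth` (arguments to [synth_config()]) and `out_dir`.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return Tibble of written manifest paths, invisibly.
#' @export
run_synth <- function(config = list(), out_dir = config$out_dir %||% "synth_run") {
  scfg <- do.call(synth_config, config$synth %||% list())
  cohort <- make_cohort(n_subjects = config$n_subjects %||% 2,
                        sessions_each = config$sessions_each %||% 1,
                        base_seed = config$seed %||% 1L, cfg = scfg)
  write_run_config(config, out_dir)
  rows <- map(seq_len(nrow(cohort)), function(i) {
    ses <- cohort$session_obj[[i]]
    d <- file.path(out_dir, paste0(ses$subject_id, "_", ses$session_id))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write_beats(ses$beats, file.path(d, "beats.csv"))
    write_vitals(ses$vitals, file.path(d, "vitals.csv"))
    write_hypnogram(ses$hypnogram, file.path(d, "hypnogram.csv"))
    if (!is.null(ses$audio)) write_wav(ses$audio, file.path(d, "audio.wav"))
    manifest <- list(subject_id = ses$subject_id, session_id = ses$session_id,
                     files = c(list(beats = "beats.csv", vitals = "vitals.csv",
                                    hypnogram = "hypnogram.csv"),
                               if (!is.null(ses$audio)) list(audio = "audio.wav")),
                     offsets = list(beats = 0, vitals = 0, audio = 0))
    mpath <- file.path(d, "manifest.yaml")
    yaml::write_yaml(manifest, mpath)
    tibble(subject = ses$subject_id, session = ses$session_id, manifest = mpath)
  })
  invisible(bind_rows(rows))
}

#' Compute feature matrices for a set of session manifests
#'
#' @param config List with `manifests` (character vector of manifest
#'   paths), optional `features` (arguments to [feature_config()]) and
#'   `out_dir`.
#' @param out_dir Output directory.
#' @return Tibble `subject, session, features_csv`, invisibly; each CSV
#'   has a sidecar `feature_dictionary.json`.
#' @export
run_features <- function(config, out_dir = config$out_dir %||% "features_run") {
  fcfg <- do.call(feature_config, config$features %||% list())
  write_run_config(config, out_dir)
  jsonlite::write_json(feature_dictionary(),
                       file.path(out_dir, "feature_dictionary.json"))
  rows <- map(config$manifests, function(m) {
    ses <- read_session(m)
    fm <- assemble_features(ses, fcfg)
    path <- file.path(out_dir, sprintf("%s_%s_features.csv",
                                       ses$subject_id, ses$session_id))
    readr::write_csv(as_tibble(as.data.frame(fm)), path)
    tibble(subject = ses$subject_id, session = ses$session_id,
           features_csv = path)
  })
  invisible(bind_rows(rows))
}

#' Train and evaluate under leave-one-subject-out cross-validation
#'
#' Either generates a synthetic cohort (when `config$synthetic = TRUE`)
#' or consumes `config$manifests`, assembles features, runs the LOSO
#' loop and writes tidy metric CSVs (fold, class, metric, value),
#' confusion matrices and a JSON summary into the run directory.
#'
#' @param config List: `seed`, `synthetic`, `n_subjects`,
#'   `sessions_each`, `synth`, `features`, `model` (arguments to
#'   [staging_config()]), `hyper` (arguments to [staging_hyper()]),
#'   `out_dir`.
#' @param out_dir Output directory.
#' @return The `loso_report`, invisibly.
#' @export
run_train_eval <- function(config = list(),
                           out_dir = config$out_dir %||% "train_eval_run") {
  seed <- config$seed %||% 1L
  fcfg <- do.call(feature_config, config$features %||% list())
  if (isTRUE(config$synthetic) || is.null(config$manifests)) {
    scfg <- do.call(synth_config, config$synth %||% list())
    cohort <- make_cohort(n_subjects = config$n_subjects %||% 3,
                          sessions_each = config$sessions_each %||% 1,
                          base_seed = seed, cfg = scfg)
  } else {
    cohort <- bind_rows(map(config$manifests, function(m) {
      ses <- read_session(m)
      tibble(subject = ses$subject_id, session = ses$session_id,
             session_obj = list(ses))
    }))
  }
  feats <- cohort_features(cohort, fcfg)
  if (any(map_lgl_null(feats$labels))) {
    abort("train-eval requires labelled sessions (hypnograms)",
          class = "bcgsleep_parameter_error")
  }
  mcfg <- do.call(staging_config, config$model %||% list())
  hyper <- do.call(staging_hyper, config$hyper %||% list())
  report <- loso_train_eval(feats, config = mcfg, hyper = hyper, seed = seed)
  write_run_config(config, out_dir)
  write_report(report, out_dir)
  invisible(report)
}

#' Write a LOSO report to disk
#'
#' Tidy metrics CSV (`scheme, fold, class, metric, value`), pooled
#' confusion matrices and a JSON summary.
#'
#' @param report A `loso_report`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tidy_all <- tidy(report)
  readr::write_csv(tidy_all, file.path(out_dir, "metrics.csv"))
  for (scheme in c("report_5class", "report_3class")) {
    cm <- report[[scheme]]$pooled_cm
    readr::write_csv(as_tibble(as.data.frame.matrix(cm), rownames = "ref"),
                     file.path(out_dir, paste0(sub("report_", "confusion_", scheme), ".csv")))
  }
  jsonlite::write_json(glance(report), file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
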