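# Session containers and delimited-text I/O for all recording streams.
# All streams live on one session clock (seconds from session start) and
# the 30-s epoch grid is derived from that clock with 0-based indices and
# half-open windows [k*30, (k+1)*30).

EPOCH_S <- 30
STAGES_5 <- c("W", "N1", "N2", "N3", "REM")
STAGES_3 <- c("W", "NREM", "REM")

#' Beat-interval series
#'
#' Timestamped beat-to-beat (JJ) intervals from the BCG bed sensor: the
#' substrate of all HRV computations.
#'
#' @param onset_s Beat onset times in seconds from session start, strictly
#'   increasing.
#' @param jj_ms JJ interval in milliseconds, strictly positive.
#' @return A tibble of class `beat_series` with columns `t`, `jj_ms`.
#' @export
beat_series <- function(onset_s, jj_ms) {
  onset_s <- as.double(onset_s)
  jj_ms <- as.double(jj_ms)
  if (length(onset_s) != length(jj_ms)) {
    abort("onset_s and jj_ms must have equal length", class = "bcgsleep_invariant_error")
  }
  bad <- which(!(jj_ms > 0) | !is.finite(jj_ms))
  if (length(bad)) {
    abort(sprintf("non-positive or non-finite JJ interval at row %d", bad[1]),
          class = "bcgsleep_invariant_error")
  }
  if (length(onset_s) > 1 && any(diff(onset_s) <= 0)) {
    abort(sprintf("beat onset times not strictly increasing at row %d",
                  which(diff(onset_s) <= 0)[1] + 1L),
          class = "bcgsleep_invariant_error")
  }
  out <- tibble(t = onset_s, jj_ms = jj_ms)
  class(out) <- c("beat_series", class(out))
  out
}

#' 1 Hz vitals series
#'
#' Device-reported vitals on a uniform 1 Hz grid: heart rate (BPM),
#' BCG-derived respiration rate (breaths/min), stroke-volume amplitude
#' (device units) and optionally the device's own HRV output (ms).
#'
#' @param t Seconds from session start.
#' @param hr,bdr,sv Numeric vectors; non-negative where present (NA marks a
#'   gap before interpolation).
#' @param hrv Optional device HRV (ms).
#' @return A tibble of class `vitals_series` with columns `t,hr,bdr,sv,hrv`.
#' @export
vitals_series <- function(t, hr, bdr, sv, hrv = NULL) {
  n <- length(t)
  if (is.null(hrv)) hrv <- rep(NA_real_, n)
  stopifnot(length(hr) == n, length(bdr) == n, length(sv) == n, length(hrv) == n)
  for (nm in c("hr", "bdr", "sv")) {
    v <- get(nm)
    if (any(v < 0, na.rm = TRUE)) {
      abort(sprintf("negative %s value", nm), class = "bcgsleep_invariant_error")
    }
  }
  out <- tibble(t = as.double(t), hr = as.double(hr), bdr = as.double(bdr),
                sv = as.double(sv), hrv = as.double(hrv))
  class(out) <- c("vitals_series", class(out))
  out
}

#' Audio recording
#'
#' Mono PCM samples with their sample rate; amplitudes are nominally in
#' `[-1, 1]`.
#'
#' @param samples Numeric vector of samples.
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `audio_recording`.
#' @export
audio_recording <- function(samples, sample_rate) {
  if (!is.numeric(samples)) abort("samples must be numeric")
  if (!(is.numeric(sample_rate) && length(sample_rate) == 1 && sample_rate > 0)) {
    abort("sample_rate must be a positive scalar", class = "bcgsleep_invariant_error")
  }
  structure(list(samples = as.double(samples), sample_rate = as.double(sample_rate)),
            class = "audio_recording")
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording: %.1f s @ %g Hz>\n",
              length(x$samples) / x$sample_rate, x$sample_rate))
  invisible(x)
}

#' Hypnogram
#'
#' Per-epoch sleep-stage labels on the 30-s epoch grid. Stages are the
#' 5-class AASM alphabet `W, N1, N2, N3, REM` (or the 3-class alphabet
#' `W, NREM, REM` after relabelling).
#'
#' @param stage Character vector of stage labels for epochs `0, 1, ...`.
#' @param alphabet Allowed label set, 5-class by default.
#' @return A tibble of class `hypnogram` with columns `epoch`, `stage`.
#' @export
hypnogram <- function(stage, alphabet = STAGES_5) {
  stage <- as.character(stage)
  bad <- which(!stage %in% alphabet)
  if (length(bad)) {
    abort(sprintf("stage '%s' at epoch %d outside alphabet {%s}",
                  stage[bad[1]], bad[1] - 1L, paste(alphabet, collapse = ",")),
          class = "bcgsleep_invariant_error")
  }
  out <- tibble(epoch = seq_along(stage) - 1L, stage = stage)
  attr(out, "alphabet") <- alphabet
  class(out) <- c("hypnogram", class(out))
  out
}

#' Assemble a synchronized recording session
#'
#' Holds all streams of one sleep recording on a single session clock.
#' Beat intervals and vitals are mandatory; audio and a reference
#' hypnogram are optional (features can be computed without labels, and
#' BCG-only feature subsets are possible). The session duration is the
#' largest whole number of 30-s epochs covered by every mandatory stream.
#'
#' @param subject_id,session_id Identifiers.
#' @param beats A [beat_series()].
#' @param vitals A [vitals_series()].
#' @param audio Optional [audio_recording()].
#' @param hypnogram Optional [hypnogram()].
#' @return An object of class `sleep_session`.
#' @export
sleep_session <- function(subject_id, session_id, beats, vitals,
                          audio = NULL, hypnogram = NULL) {
  stopifnot(inherits(beats, "beat_series"), inherits(vitals, "vitals_series"))
  # stream extents: a 1 Hz vitals sample covers one second; the beat
  # stream extends to the end of its last interval
  dur <- min(max(vitals$t) + 1,
             max(beats$t) + beats$jj_ms[nrow(beats)] / 1000)
  if (!is.null(audio)) dur <- min(dur, length(audio$samples) / audio$sample_rate)
  n_epochs <- floor(dur / EPOCH_S)
  if (n_epochs < 1) {
    abort("session shorter than one 30-s epoch", class = "bcgsleep_empty_grid_error")
  }
  dur <- n_epochs * EPOCH_S
  beats <- beats[beats$t < dur, ]
  vitals <- vitals[vitals$t < dur, ]
  if (!is.null(audio)) {
    keep <- seq_len(min(length(audio$samples), round(dur * audio$sample_rate)))
    audio <- audio_recording(audio$samples[keep], audio$sample_rate)
  }
  if (!is.null(hypnogram)) hypnogram <- hypnogram[hypnogram$epoch < n_epochs, ]
  structure(list(subject_id = subject_id, session_id = session_id,
                 beats = beats, vitals = vitals, audio = audio,
                 hypnogram = hypnogram, duration_s = dur, n_epochs = n_epochs),
            class = "sleep_session")
}

#' @export
print.sleep_session <- function(x, ...) {
  cat(sprintf("<sleep_session %s/%s: %d epochs (%.0f s), %d beats%s%s>\n",
              x$subject_id, x$session_id, x$n_epochs, x$duration_s,
              nrow(x$beats),
              if (is.null(x$audio)) "" else ", audio",
              if (is.null(x$hypnogram)) "" else ", hypnogram"))
  invisible(x)
}

#' 30-s epoch grid of a session
#'
#' @param session A [sleep_session()].
#' @return Tibble with `epoch` (0-based), `start_s`, `end_s`; windows are
#'   half-open `[start, end)` and `n = floor(duration / 30)`.
#' @export
epoch_grid <- function(session) {
  stopifnot(inherits(session, "sleep_session"))
  k <- seq_len(session$n_epochs) - 1L
  tibble(epoch = k, start_s = k * EPOCH_S, end_s = (k + 1) * EPOCH_S)
}

shift_times <- function(t, offset) t - offset

shift_audio <- function(audio, offset) {
  if (offset == 0) return(audio)
  n_shift <- round(offset * audio$sample_rate)
  x <- audio$samples
  if (n_shift > 0) {
    x <- x[-seq_len(min(n_shift, length(x)))]
  } else if (n_shift < 0) {
    x <- c(numeric(-n_shift), x)
  }
  audio_recording(x, audio$sample_rate)
}

read_stream_csv <- function(path, cols) {
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(sprintf("cannot parse '%s': %s", path, conditionMessage(e)),
                              class = "bcgsleep_parse_error")
  )
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    abort(sprintf("'%s' lacks column(s) %s", path, paste(missing_cols, collapse = ", ")),
          class = "bcgsleep_parse_error")
  }
  df
}

#' Read a beat-interval CSV (`t,jj_ms`)
#' @param path CSV path.
#' @return A [beat_series()].
#' @export
read_beats <- function(path) {
  df <- read_stream_csv(path, c("t", "jj_ms"))
  tryCatch(beat_series(df$t, df$jj_ms), error = function(e) {
    abort(sprintf("'%s': %s", path, conditionMessage(e)), class = "bcgsleep_parse_error")
  })
}

#' Read a vitals CSV (`t,hr,bdr,sv[,hrv]`)
#' @param path CSV path.
#' @return A [vitals_series()].
#' @export
read_vitals <- function(path) {
  df <- read_stream_csv(path, c("t", "hr", "bdr", "sv"))
  vitals_series(df$t, df$hr, df$bdr, df$sv, if ("hrv" %in% names(df)) df$hrv)
}

#' Write a vitals series to CSV
#' @param vitals A [vitals_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vitals <- function(vitals, path) {
  readr::write_csv(as_tibble(as.data.frame(vitals)), path)
  invisible(path)
}

#' Write a beat series to CSV
#' @param beats A [beat_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beats <- function(beats, path) {
  readr::write_csv(as_tibble(as.data.frame(beats)), path)
  invisible(path)
}

#' Read a hypnogram CSV (`epoch,stage`)
#' @param path CSV path.
#' @param alphabet Allowed label set.
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, alphabet = STAGES_5) {
  df <- read_stream_csv(path, c("epoch", "stage"))
  df <- arrange(df, .data$epoch)
  if (nrow(df) && !identical(as.integer(df$epoch), seq_len(nrow(df)) - 1L)) {
    abort(sprintf("'%s': epoch indices not contiguous from 0", path),
          class = "bcgsleep_parse_error")
  }
  hypnogram(df$stage, alphabet = alphabet)
}

#' Write a hypnogram to CSV
#'
#' Round-trips exactly through [read_hypnogram()].
#'
#' @param h A [hypnogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  readr::write_csv(as_tibble(as.data.frame(h)), path)
  invisible(path)
}

#' Read a full session from a manifest
#'
#' The manifest is a YAML (or JSON) file naming the per-stream files and
#' synchronization offsets. A sample in stream `s` recorded at time `t`
#' appears at session time `t - offset[s]`; explicit offsets replace
#' hardware event-marker synchronization. Relative paths are resolved
#' against the manifest's directory.
#'
#' Manifest fields: `subject_id`, `session_id`, `files:` (`beats`,
#' `vitals`, optional `audio`, optional `hypnogram`) and optional
#' `offsets:` (seconds per stream, default 0).
#'
#' @param manifest Path to the manifest file, or an equivalent named list.
#' @param base_dir Directory for resolving relative paths (defaults to the
#'   manifest's directory).
#' @return A [sleep_session()].
#' @export
read_session <- function(manifest, base_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- yaml::read_yaml(manifest)
  }
  if (is.null(base_dir)) base_dir <- "."
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
  off <- function(nm) {
    o <- manifest$offsets[[nm]]
    if (is.null(o)) 0 else as.double(o)
  }
  stopifnot(!is.null(manifest$files$beats), !is.null(manifest$files$vitals))
  beats <- read_beats(resolve(manifest$files$beats))
  beats$t <- shift_times(beats$t, off("beats"))
  beats <- beats[beats$t >= 0, ]
  vitals <- read_vitals(resolve(manifest$files$vitals))
  vitals$t <- shift_times(vitals$t, off("vitals"))
  vitals <- vitals[vitals$t >= 0, ]
  audio <- NULL
  if (!is.null(manifest$files$audio)) {
    audio <- shift_audio(read_wav(resolve(manifest$files$audio)), off("audio"))
  }
  hyp <- NULL
  if (!is.null(manifest$files$hypnogram)) {
    hyp <- read_hypnogram(resolve(manifest$files$hypnogram))
  }
  sleep_session(manifest$subject_id %||% "unknown",
                manifest$session_id %||% "unknown",
                beat_series(beats$t, beats$jj_ms),
                vitals_series(vitals$t, vitals$hr, vitals$bdr, vitals$sv, vitals$hrv),
                audio = audio, hypnogram = hyp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
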