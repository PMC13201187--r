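# Synthetic session generator: Markov hypnogram, stage-conditioned beat
# intervals with respiration-coupled modulation, 1 Hz vitals with
# dropouts, and breathing audio over a pink-noise carrier. All generation
# is a pure function of (config, seed), so the whole pipeline trains and
# evaluates without any external recordings.

#' Synthetic-session configuration
#'
#' Stage-dependent cardiorespiratory parameters. Heart rate slows and the
#' high-frequency (respiratory) beat-interval modulation strengthens with
#' deeper non-REM sleep, while the low-frequency component dominates in
#' wake/REM; the coupling gain scales how strongly respiration modulates
#' both the beat intervals and the reported respiration-rate stream,
#' which is what makes cardiopulmonary coupling informative. The
#' `"separated"` preset widens the between-stage parameter gaps (an
#' idealized, well-separated regime for recovery experiments).
#'
#' @param preset `"default"` or `"separated"`.
#' @param duration_s Session length in seconds (default 10800, about 3 h,
#'   i.e. roughly 360 30-s epochs).
#' @param transition 5x5 stage transition matrix (rows sum to 1, order
#'   W, N1, N2, N3, REM).
#' @param hr_bpm,lf_amp_ms,hf_amp_ms,resp_rate,coupling Named per-stage
#'   numeric vectors.
#' @param jj_noise_ms SD of the white beat-interval noise (ms).
#' @param dropout_rate Fraction of 1 Hz vitals samples lost.
#' @param audio_sr Audio sample rate (default 8000 Hz; all audio features
#'   live below 4 kHz).
#' @param breath_amp,snore_amp,noise_floor Audio amplitudes.
#' @param snore_prob Probability that a breath in N2/N3 carries a
#'   low-frequency snore burst.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(preset = c("default", "separated"),
                         duration_s = 10800,
                         transition = NULL,
                         hr_bpm = NULL, lf_amp_ms = NULL, hf_amp_ms = NULL,
                         resp_rate = NULL, coupling = NULL,
                         jj_noise_ms = 10, dropout_rate = 0.01,
                         audio_sr = 8000, breath_amp = 0.10,
                         snore_amp = 0.20, noise_floor = 0.005,
                         snore_prob = 0.15) {
  preset <- match.arg(preset)
  if (duration_s < 600) abort("duration_s must be >= 600", class = "bcgsleep_parameter_error")
  st <- STAGES_5
  if (is.null(transition)) {
    transition <- rbind(
      W   = c(0.80, 0.15, 0.04, 0.00, 0.01),
      N1  = c(0.05, 0.70, 0.22, 0.01, 0.02),
      N2  = c(0.02, 0.03, 0.85, 0.07, 0.03),
      N3  = c(0.01, 0.01, 0.10, 0.87, 0.01),
      REM = c(0.03, 0.04, 0.05, 0.00, 0.88))
    colnames(transition) <- st
  }
  if (is.null(rownames(transition))) rownames(transition) <- st
  if (is.null(colnames(transition))) colnames(transition) <- st
  if (any(abs(rowSums(transition) - 1) > 1e-8) || any(transition < 0)) {
    abort("transition rows must be nonnegative and sum to 1",
          class = "bcgsleep_parameter_error")
  }
  defaults <- if (preset == "default") {
    list(hr = c(W = 72, N1 = 64, N2 = 60, N3 = 56, REM = 68),
         lf = c(W = 50, N1 = 40, N2 = 30, N3 = 15, REM = 45),
         hf = c(W = 15, N1 = 25, N2 = 35, N3 = 45, REM = 20),
         rr = c(W = 16, N1 = 14, N2 = 13, N3 = 12, REM = 15),
         cg = c(W = 0.3, N1 = 1.0, N2 = 1.5, N3 = 2.0, REM = 0.5))
  } else {
    list(hr = c(W = 82, N1 = 68, N2 = 58, N3 = 48, REM = 74),
         lf = c(W = 70, N1 = 45, N2 = 25, N3 = 10, REM = 60),
         hf = c(W = 10, N1 = 30, N2 = 45, N3 = 60, REM = 15),
         rr = c(W = 17, N1 = 14.5, N2 = 13, N3 = 11, REM = 15.5),
         cg = c(W = 0.2, N1 = 1.0, N2 = 1.8, N3 = 2.5, REM = 0.4))
  }
  hr_bpm <- hr_bpm %||% defaults$hr
  lf_amp_ms <- lf_amp_ms %||% defaults$lf
  hf_amp_ms <- hf_amp_ms %||% defaults$hf
  resp_rate <- resp_rate %||% defaults$rr
  coupling <- coupling %||% defaults$cg
  for (v in list(hr_bpm, lf_amp_ms, hf_amp_ms, resp_rate, coupling)) {
    stopifnot(identical(sort(names(v)), sort(st)))
  }
  if (any(60000 / hr_bpm - lf_amp_ms - coupling * hf_amp_ms - 6 * jj_noise_ms <= 0)) {
    abort("parameters can produce nonpositive JJ intervals",
          class = "bcgsleep_parameter_error")
  }
  structure(list(preset = preset, duration_s = duration_s,
                 transition = transition, hr_bpm = hr_bpm,
                 lf_amp_ms = lf_amp_ms, hf_amp_ms = hf_amp_ms,
                 resp_rate = resp_rate, coupling = coupling,
                 jj_noise_ms = jj_noise_ms, dropout_rate = dropout_rate,
                 audio_sr = audio_sr, breath_amp = breath_amp,
                 snore_amp = snore_amp, noise_floor = noise_floor,
                 snore_prob = snore_prob),
            class = "synth_config")
}

LF_OSC_HZ <- 0.09  # fixed LF oscillation, inside the 0.04-0.15 Hz band

#' Sample a Markov hypnogram
#'
#' First-order Markov stage sequence at the 30-s epoch pitch, starting in
#' wake. The default transition matrix makes N2 the most frequent sleep
#' stage and puts wake bouts at the session edges.
#'
#' @param cfg A [synth_config()].
#' @param n_epochs Number of epochs (default from `cfg$duration_s`).
#' @return A [hypnogram()].
#' @export
sample_hypnogram <- function(cfg, n_epochs = floor(cfg$duration_s / EPOCH_S)) {
  st <- STAGES_5
  P <- cfg$transition
  stages <- character(n_epochs)
  cur <- "W"
  for (k in seq_len(n_epochs)) {
    stages[k] <- cur
    cur <- sample(st, 1, prob = P[cur, ])
  }
  hypnogram(stages)
}

stage_at <- function(hyp, t) hyp$stage[pmin(nrow(hyp), floor(t / EPOCH_S) + 1L)]

#' Generate stage-conditioned beat intervals and vitals
#'
#' Beat intervals follow
#' `JJ = 60000 / HR(stage) + A_LF sin(2 pi 0.09 t + phi1)
#'  + g A_HF sin(2 pi f_resp t + phi2) + noise`,
#' with `f_resp` the stage's respiratory frequency and `g` the stage
#' coupling gain; beat onsets accumulate from the intervals. The 1 Hz
#' vitals carry heart rate, a respiration-rate stream with a small
#' coupling-scaled within-breath oscillation (phase-locked to the beat
#' modulation), and a stroke-volume amplitude modulated at the
#' respiratory frequency. Vitals samples are dropped at the configured
#' rate to emulate network loss.
#'
#' @param hyp A [hypnogram()].
#' @param cfg A [synth_config()].
#' @return List with `beats` ([beat_series()]) and `vitals`
#'   ([vitals_series()] with gaps as NA rows removed).
#' @export
synth_cardiac <- function(hyp, cfg) {
  dur <- nrow(hyp) * EPOCH_S
  phi1 <- runif(1, 0, 2 * pi); phi2 <- runif(1, 0, 2 * pi)
  # beats
  t <- 0
  n_guess <- ceiling(dur * (max(cfg$hr_bpm) + 30) / 60) + 10
  tt <- numeric(n_guess); jj <- numeric(n_guess)
  i <- 0L
  while (t < dur) {
    s <- stage_at(hyp, t)
    f_resp <- cfg$resp_rate[[s]] / 60
    val <- 60000 / cfg$hr_bpm[[s]] +
      cfg$lf_amp_ms[[s]] * sin(2 * pi * LF_OSC_HZ * t + phi1) +
      cfg$coupling[[s]] * cfg$hf_amp_ms[[s]] * sin(2 * pi * f_resp * t + phi2) +
      rnorm(1, 0, cfg$jj_noise_ms)
    val <- max(val, 250)
    i <- i + 1L
    tt[i] <- t + val / 1000
    jj[i] <- val
    t <- tt[i]
  }
  beats <- beat_series(tt[seq_len(i)], jj[seq_len(i)])
  # vitals at 1 Hz
  tv <- seq(0, dur - 1)
  sv_stage <- stage_at(hyp, tv)
  f_resp_v <- cfg$resp_rate[sv_stage] / 60
  cg_v <- cfg$coupling[sv_stage]
  hr_v <- cfg$hr_bpm[sv_stage] + rnorm(length(tv), 0, 1)
  bdr_v <- cfg$resp_rate[sv_stage] +
    1.5 * cg_v * sin(2 * pi * f_resp_v * tv + phi2) +
    rnorm(length(tv), 0, 0.3)
  sv_v <- 50 * (1 + 0.3 * sin(2 * pi * f_resp_v * tv + phi2)) +
    rnorm(length(tv), 0, 1)
  keep <- runif(length(tv)) >= cfg$dropout_rate
  vitals <- vitals_series(tv[keep], pmax(hr_v[keep], 0),
                          pmax(bdr_v[keep], 0), pmax(sv_v[keep], 0))
  list(beats = beats, vitals = vitals)
}

# pink-ish noise via the Paul Kellet economy filter (three parallel
# one-pole sections, vectorized through the recursive filter)
pink_noise <- function(n) {
  w <- rnorm(n)
  b0 <- as.numeric(stats::filter(w * 0.0990460, 0.99765, method = "recursive"))
  b1 <- as.numeric(stats::filter(w * 0.2965164, 0.96300, method = "recursive"))
  b2 <- as.numeric(stats::filter(w * 1.0526913, 0.57000, method = "recursive"))
  (b0 + b1 + b2 + w * 0.1848) / 4
}

#' Generate breathing audio for a hypnogram
#'
#' Per-breath Hann-shaped amplitude envelopes at the stage's respiratory
#' period gate a pink-noise carrier; N2/N3 breaths optionally add a
#' low-frequency (60-300 Hz) snore burst, and a stationary noise floor
#' underlies everything.
#'
#' @param hyp A [hypnogram()].
#' @param cfg A [synth_config()].
#' @return An [audio_recording()] at `cfg$audio_sr`.
#' @export
synth_audio <- function(hyp, cfg) {
  sr <- cfg$audio_sr
  dur <- nrow(hyp) * EPOCH_S
  n <- dur * sr
  x <- cfg$noise_floor * rnorm(n)
  if (cfg$breath_amp > 0 || cfg$snore_amp > 0) {
    carrier <- pink_noise(n)
    t0 <- 0
    while (t0 < dur) {
      s <- stage_at(hyp, t0)
      period <- 60 / cfg$resp_rate[[s]]
      breath_len <- 0.45 * period
      i0 <- floor(t0 * sr) + 1
      i1 <- min(floor((t0 + breath_len) * sr), n)
      if (i1 > i0) {
        env <- hann_window(i1 - i0 + 1)
        idx <- i0:i1
        x[idx] <- x[idx] + cfg$breath_amp * env * carrier[idx]
        if (cfg$snore_amp > 0 && s %in% c("N2", "N3") &&
            runif(1) < cfg$snore_prob) {
          tt <- (idx - i0) / sr
          snore <- sin(2 * pi * 90 * tt) + 0.5 * sin(2 * pi * 180 * tt) +
            0.25 * sin(2 * pi * 270 * tt)
          x[idx] <- x[idx] + cfg$snore_amp * env * snore
        }
      }
      t0 <- t0 + period
    }
  }
  audio_recording(x, sr)
}

#' Generate one complete synthetic session
#'
#' @param cfg A [synth_config()].
#' @param seed Integer seed (below 2^31).
#' @param subject_id,session_id Identifiers.
#' @param audio Generate the audio stream (default TRUE).
#' @return A [sleep_session()] carrying its ground-truth hypnogram.
#' @export
synth_session <- function(cfg = synth_config(), seed = 1L,
                          subject_id = "S1", session_id = "ses1",
                          audio = TRUE) {
  set.seed(seed)
  hyp <- sample_hypnogram(cfg)
  card <- synth_cardiac(hyp, cfg)
  aud <- if (audio) synth_audio(hyp, cfg) else NULL
  sleep_session(subject_id, session_id, card$beats, card$vitals,
                audio = aud, hypnogram = hyp)
}

#' Generate a multi-subject cohort
#'
#' Per-subject parameter jitter (heart-rate and respiration offsets,
#' amplitude scaling) emulates between-subject differences; generation is
#' deterministic per `(base_seed, subject, session)`.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param sessions_each Sessions per subject.
#' @param base_seed Integer seed.
#' @param cfg A [synth_config()] holding the cohort-level defaults.
#' @param audio Generate audio streams.
#' @return Tibble `subject, session, session_obj` (list of
#'   [sleep_session()]s, each with its ground-truth hypnogram).
#' @export
make_cohort <- function(n_subjects = 9, sessions_each = 3, base_seed = 1L,
                        cfg = synth_config(), audio = TRUE) {
  plan <- cohort_plan(n_subjects, sessions_each, base_seed, cfg)
  plan$session_obj <- map(seq_len(nrow(plan)), function(i) {
    synth_session(plan$cfg_s[[i]], seed = plan$seed[i],
                  subject_id = plan$subject[i], session_id = plan$session[i],
                  audio = audio)
  })
  select(plan, "subject", "session", "session_obj")
}

# deterministic per-subject parameter jitter and per-session seeds
cohort_plan <- function(n_subjects, sessions_each, base_seed, cfg) {
  stopifnot(n_subjects >= 2)
  set.seed(base_seed)
  jit <- tibble(subject = paste0("S", seq_len(n_subjects)),
                hr_off = rnorm(n_subjects, 0, 3),
                rr_off = rnorm(n_subjects, 0, 0.8),
                amp_scale = exp(rnorm(n_subjects, 0, 0.15)))
  rows <- list()
  for (s in seq_len(n_subjects)) {
    cfg_s <- cfg
    cfg_s$hr_bpm <- cfg$hr_bpm + jit$hr_off[s]
    cfg_s$resp_rate <- pmax(cfg$resp_rate + jit$rr_off[s], 6)
    cfg_s$lf_amp_ms <- cfg$lf_amp_ms * jit$amp_scale[s]
    cfg_s$hf_amp_ms <- cfg$hf_amp_ms * jit$amp_scale[s]
    for (k in seq_len(sessions_each)) {
      rows[[length(rows) + 1]] <- tibble(
        subject = jit$subject[s], session = paste0("ses", k),
        cfg_s = list(cfg_s),
        seed = (base_seed + 7919L * s + 104729L * k) %% .Machine$integer.max)
    }
  }
  bind_rows(rows)
}

#' Generate a cohort and extract features, one session at a time
#'
#' Identical output to `make_cohort()` followed by [cohort_features()]
#' (same seeds, same jitter), but each session — audio included — is
#' discarded as soon as its features and labels are extracted, so peak
#' memory stays at a single session regardless of cohort size.
#'
#' @inheritParams make_cohort
#' @param config A [feature_config()].
#' @param verbose Print progress.
#' @return Tibble `subject, session, features, labels` as from
#'   [cohort_features()].
#' @export
synth_cohort_features <- function(n_subjects = 9, sessions_each = 3,
                                  base_seed = 1L, cfg = synth_config(),
                                  audio = TRUE, config = feature_config(),
                                  verbose = FALSE) {
  plan <- cohort_plan(n_subjects, sessions_each, base_seed, cfg)
  rows <- map(seq_len(nrow(plan)), function(i) {
    if (verbose) message(sprintf("session %d/%d (%s/%s)", i, nrow(plan),
                                 plan$subject[i], plan$session[i]))
    ses <- synth_session(plan$cfg_s[[i]], seed = plan$seed[i],
                         subject_id = plan$subject[i],
                         session_id = plan$session[i], audio = audio)
    fm <- assemble_features(ses, config)
    lab <- ses$hypnogram$stage[seq_len(nrow(fm))]
    rm(ses); gc(verbose = FALSE)
    tibble(subject = plan$subject[i], session = plan$session[i],
           features = list(fm), labels = list(lab))
  })
  bind_rows(rows)
}
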