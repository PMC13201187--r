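# Respiration-related features from bedside audio: spectrogram,
# spectral-centroid instantaneous frequency, autocorrelation of the
# breathing envelope, respiration cycle period/intensity/consistency,
# band energies and sound-pressure-level statistics, plus a spectral
# subtraction noise gate.

AUDIO_NFFT <- 2048L
AUDIO_HOP <- 1024L  # 50% overlap

#' Power spectrogram of an audio segment
#'
#' Short-time power spectra with 2048-sample Hann frames and 50% overlap
#' (hop 1024); a 30-s segment at rate `fs` yields
#' `floor((30 fs - 2048)/1024) + 1` frames.
#'
#' @param audio An [audio_recording()] (or segment thereof).
#' @return List with `power` (frames x bins, one-sided), `freq` (Hz),
#'   `time` (frame centre, s) and `frame_rate` (frames per second,
#'   `fs / 1024`).
#' @export
audio_spectrogram <- function(audio) {
  stopifnot(inherits(audio, "audio_recording"))
  st <- stft_frames(audio$samples, AUDIO_NFFT, AUDIO_HOP)
  n_half <- AUDIO_NFFT / 2 + 1L
  p <- Mod(st$spec[, seq_len(n_half), drop = FALSE])^2
  list(power = p,
       freq = (seq_len(n_half) - 1) * audio$sample_rate / AUDIO_NFFT,
       time = (st$starts - 1 + AUDIO_NFFT / 2) / audio$sample_rate,
       frame_rate = audio$sample_rate / AUDIO_HOP)
}

#' Instantaneous (spectral-centroid) frequency per frame
#'
#' `f_inst(t) = sum(f * P(t, f)) / sum(P(t, f))` over the spectrogram
#' bins; bounded by the lowest and highest powered bin of each frame.
#' Zero-power frames are NA.
#'
#' @param spec A spectrogram as returned by [audio_spectrogram()].
#' @return Numeric vector, one centroid (Hz) per frame.
#' @export
instantaneous_frequency <- function(spec) {
  tot <- rowSums(spec$power)
  centroid <- as.numeric(spec$power %*% spec$freq)
  ifelse(tot > 0, centroid / tot, NA_real_)
}

#' Normalized autocorrelation sequence
#'
#' `r_k = c_k / c_0` with `c_k` the lag-k autocovariance
#' `(1/T) * sum_(t=1)^(T-k) (y_t - mean)(y_(t+k) - mean)`; `r_0 = 1`
#' exactly and `|r_k| <= 1`.
#'
#' @param y Numeric series (an audio-derived envelope, typically).
#' @param lag_max Largest lag to return (default `length(y) - 1`).
#' @return Tibble `lag, r`; flagged `ok = FALSE` attribute-free NA tibble
#'   when the series has zero variance.
#' @export
autocorrelation_rk <- function(y, lag_max = length(y) - 1L) {
  if (length(y) < 2) abort("series too short", class = "bcgsleep_parameter_error")
  if (!all(is.finite(y)) || var(y) == 0) {
    return(tibble(lag = 0:lag_max, r = NA_real_))
  }
  a <- stats::acf(y, lag.max = lag_max, plot = FALSE, demean = TRUE)
  tibble(lag = 0:lag_max, r = as.numeric(a$acf))
}

# Breathing envelope at the spectrogram frame rate: per-hop RMS
# (rectification) smoothed by a low-pass well below the frame Nyquist,
# which keeps 3-8 s breath periods and discards the audio carrier.
respiration_envelope <- function(audio, lowpass_hz = 2) {
  x <- audio$samples
  n_blocks <- length(x) %/% AUDIO_HOP
  if (n_blocks < 4) abort("segment too short for an envelope",
                          class = "bcgsleep_parameter_error")
  blocks <- matrix(x[seq_len(n_blocks * AUDIO_HOP)], nrow = AUDIO_HOP)
  env <- sqrt(colMeans(blocks^2))
  frame_rate <- audio$sample_rate / AUDIO_HOP
  wc <- min(0.9, lowpass_hz / (frame_rate / 2))
  bf <- signal::butter(2, wc)
  env_s <- as.numeric(signal::filtfilt(bf, env))
  list(env = env_s, frame_rate = frame_rate)
}

# Local maxima with a simple topographic prominence; returns indices.
find_peaks_prominent <- function(r, min_prominence) {
  n <- length(r)
  if (n < 3) return(integer(0))
  cand <- which(r[2:(n - 1)] > r[1:(n - 2)] & r[2:(n - 1)] >= r[3:n]) + 1L
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    left <- r[seq_len(i - 1)]
    right <- r[(i + 1):n]
    higher_l <- which(left >= r[i])
    higher_r <- which(right >= r[i])
    base_l <- if (length(higher_l)) {
      seg <- left[(max(higher_l) + 1):(i - 1)]
      if (length(seg)) min(seg) else r[i]
    } else min(left)
    base_r <- if (length(higher_r)) {
      if (min(higher_r) > 1) min(right[seq_len(min(higher_r) - 1)]) else r[i]
    } else min(right)
    keep[j] <- r[i] - max(base_l, base_r) >= min_prominence
  }
  cand[keep]
}

#' Respiration cycle features from an autocorrelation sequence
#'
#' Finds positive autocorrelation peaks (excluding lag 0) within
#' physiologic breath periods; the cycle period `cp` is the first peak
#' lag converted to seconds (`t1 / frame_rate`), the cycle intensity `ci`
#' is the autocorrelation at that lag, and the cycle consistency `cc` is
#' the SD of the autocorrelation at all detected peak lags (0 for a
#' perfectly regular pattern with equal peaks). With no peak passing the
#' prominence threshold, `detected = FALSE` and features are NA.
#'
#' @param r Tibble `lag, r` from [autocorrelation_rk()] of a 30-s
#'   breathing-envelope segment.
#' @param frame_rate Envelope frame rate `F_r` (frames/s).
#' @param min_lag_s,max_lag_s Search range for the breath period
#'   (defaults 1.5-15 s, i.e. 4-40 breaths/min).
#' @param min_prominence Prominence threshold on normalized r
#'   (default 0.1).
#' @param min_height Minimum autocorrelation amplitude of an accepted
#'   peak (default 0.25): a genuine breathing envelope puts substantial
#'   mass at its period, while white-noise autocorrelations in the
#'   physiologic lag range stay well below this floor.
#' @param literal_product If TRUE, report the period as the literal
#'   frame-count x frame-rate product instead of seconds.
#' @return Tibble `cp, ci, cc, detected`.
#' @export
respiration_cycle_features <- function(r, frame_rate, min_lag_s = 1.5,
                                       max_lag_s = 15, min_prominence = 0.1,
                                       min_height = 0.25,
                                       literal_product = FALSE) {
  if (frame_rate <= 0) abort("frame_rate must be positive",
                             class = "bcgsleep_parameter_error")
  none <- tibble(cp = NA_real_, ci = NA_real_, cc = NA_real_, detected = FALSE)
  if (anyNA(r$r)) return(none)
  peaks <- find_peaks_prominent(r$r, min_prominence)
  lags <- r$lag[peaks]
  sel <- lags / frame_rate >= min_lag_s & lags / frame_rate <= max_lag_s &
    r$r[peaks] >= min_height
  peaks <- peaks[sel]
  if (!length(peaks)) return(none)
  t1 <- r$lag[peaks[1]]
  amps <- r$r[peaks]
  tibble(cp = if (literal_product) t1 * frame_rate else t1 / frame_rate,
         ci = r$r[peaks[1]],
         cc = if (length(amps) > 1) sd(amps) else 0,
         detected = TRUE)
}

#' Acoustic summary statistics of a 30-s audio segment
#'
#' Instantaneous-frequency summaries over spectrogram frames, spectral
#' energies in five bands (0-100, 100-300, 300-800, 800-2000,
#' 2000-8000 Hz, clipped at Nyquist) plus the total, and sound-pressure
#' level statistics in dB relative to digital full scale over 100-ms RMS
#' frames. Doubling the amplitude raises SPL by ~6.02 dB and scales
#' energies by 4.
#'
#' @param audio An [audio_recording()] segment.
#' @param db_floor Lower clamp for SPL values (default -120 dBFS).
#' @return One-row tibble: `instfreq_mean/sd/median/iqr`,
#'   `energy_b1..b5`, `energy_total`, `spl_mean/max/sd/rms`,
#'   `breath_count`, `lf_power_ratio`.
#' @export
acoustic_stats <- function(audio, db_floor = -120) {
  stopifnot(inherits(audio, "audio_recording"))
  spec <- audio_spectrogram(audio)
  fi <- instantaneous_frequency(spec)
  fi <- fi[is.finite(fi)]
  bands <- list(c(0, 100), c(100, 300), c(300, 800), c(800, 2000), c(2000, 8000))
  total <- sum(spec$power)
  be <- map_dbl(bands, function(b) {
    sel <- spec$freq >= b[1] & spec$freq < b[2]
    sum(spec$power[, sel, drop = FALSE])
  })
  # SPL over 100-ms RMS frames
  nf <- max(1L, round(0.1 * audio$sample_rate))
  nb <- length(audio$samples) %/% nf
  rmsv <- if (nb > 0) {
    sqrt(colMeans(matrix(audio$samples[seq_len(nb * nf)], nrow = nf)^2))
  } else sqrt(mean(audio$samples^2))
  spl <- pmax(db_floor, 20 * log10(pmax(rmsv, 10^(db_floor / 20))))
  spl_rms <- max(db_floor, 20 * log10(max(sqrt(mean(audio$samples^2)),
                                          10^(db_floor / 20))))
  # breath events: envelope peaks above an adaptive threshold
  env <- respiration_envelope(audio)
  thr <- mean(env$env) + 0.5 * sd(env$env)
  pk <- find_peaks_prominent(env$env, min_prominence = 0.25 * sd(env$env))
  pk <- pk[env$env[pk] > thr]
  if (length(pk) > 1) {
    min_gap <- 1.5 * env$frame_rate
    keep <- c(TRUE, diff(pk) >= min_gap)
    pk <- pk[keep]
  }
  tibble(instfreq_mean = if (length(fi)) mean(fi) else NA_real_,
         instfreq_sd = if (length(fi) > 1) sd(fi) else NA_real_,
         instfreq_median = if (length(fi)) median(fi) else NA_real_,
         instfreq_iqr = if (length(fi) > 1) stats::IQR(fi) else NA_real_,
         energy_b1 = be[1], energy_b2 = be[2], energy_b3 = be[3],
         energy_b4 = be[4], energy_b5 = be[5], energy_total = total,
         spl_mean = mean(spl), spl_max = max(spl),
         spl_sd = if (length(spl) > 1) sd(spl) else 0, spl_rms = spl_rms,
         breath_count = length(pk),
         lf_power_ratio = if (total > 0) (be[1] + be[2]) / total else NA_real_)
}

#' Spectral-subtraction noise gate
#'
#' Estimates a per-bin noise floor from a breath-free profile segment and
#' subtracts it (with over-subtraction factor `beta` and a small spectral
#' floor) from the short-time magnitude spectra of the recording,
#' resynthesizing by overlap-add. A zero-noise profile returns the input
#' essentially unchanged; a profile equal to a stationary input removes
#' nearly everything.
#'
#' @param audio An [audio_recording()].
#' @param profile An [audio_recording()] containing background noise only
#'   (no breaths); must not be longer than `audio`.
#' @param beta Over-subtraction factor (default 2).
#' @param floor_gain Minimum spectral gain (default 0.02, about -34 dB).
#' @return A gated [audio_recording()] of identical length.
#' @export
noise_gate <- function(audio, profile, beta = 2, floor_gain = 0.02) {
  stopifnot(inherits(audio, "audio_recording"), inherits(profile, "audio_recording"))
  if (length(profile$samples) > length(audio$samples)) {
    abort("noise profile longer than the recording", class = "bcgsleep_parameter_error")
  }
  n <- length(audio$samples)
  # pad so every sample (tail included) is covered by analysis frames
  n_pad <- (ceiling(max(n - AUDIO_NFFT, 0) / AUDIO_HOP)) * AUDIO_HOP + AUDIO_NFFT
  x_pad <- c(audio$samples, numeric(n_pad - n))
  st <- stft_frames(x_pad, AUDIO_NFFT, AUDIO_HOP)
  stp <- stft_frames(profile$samples, AUDIO_NFFT,
                     min(AUDIO_HOP, max(1L, length(profile$samples) - AUDIO_NFFT)))
  noise_mag <- colMeans(Mod(stp$spec))
  mag <- Mod(st$spec)
  gain <- pmax((mag - beta * matrix(noise_mag, nrow(mag), ncol(mag), byrow = TRUE)) /
                 pmax(mag, .Machine$double.eps), floor_gain)
  y <- istft_overlap_add(st$spec * gain, st$starts, AUDIO_NFFT, n)
  audio_recording(y, audio$sample_rate)
}
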