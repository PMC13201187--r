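# Assembly of the per-epoch 62-dimensional feature vector: 43 BCG-side
# features (time, frequency, Poincare, asymmetry, STA, entropies, DFA,
# Renyi, device surrogate, BDR/HR statistics, coupling) and 19 audio
# features. One row per 30-s epoch; missing values stay NA (never silent
# zeros) and are imputed only at model-input time.

#' Default feature-extraction configuration
#'
#' All tunable parameters of the feature pipeline in one list, suitable
#' for serialization into a run config.
#'
#' @param window_s HRV window length (s, default 300).
#' @param lf_band,hf_band HRV tachogram band edges (Hz).
#' @param cpc_lf_band,cpc_hf_band Coupling band edges (Hz).
#' @param artifact_lo_ms,artifact_hi_ms,artifact_jump_frac Beat screening
#'   thresholds.
#' @param sv_k Low-pass constant for the stroke-volume residual.
#' @param device_ratio `"hf_lf"` (as the bed sensor defines it) or
#'   `"lf_hf"`.
#' @param renyi_alpha Renyi orders kept as features.
#' @param sampen_m,sampen_r Embedding dimension and tolerance fraction.
#' @param max_gap_s Longest vitals gap interpolated.
#' @return A named list of class `feature_config`.
#' @export
feature_config <- function(window_s = 300,
                           lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.40),
                           cpc_lf_band = c(0.01, 0.10),
                           cpc_hf_band = c(0.10, 0.40),
                           artifact_lo_ms = 300, artifact_hi_ms = 2000,
                           artifact_jump_frac = 0.3,
                           sv_k = 0.1, device_ratio = "hf_lf",
                           renyi_alpha = c(0.25, 2, 5),
                           sampen_m = 2, sampen_r = 0.2,
                           max_gap_s = 30) {
  structure(list(window_s = window_s, lf_band = lf_band, hf_band = hf_band,
                 cpc_lf_band = cpc_lf_band, cpc_hf_band = cpc_hf_band,
                 artifact_lo_ms = artifact_lo_ms,
                 artifact_hi_ms = artifact_hi_ms,
                 artifact_jump_frac = artifact_jump_frac,
                 sv_k = sv_k, device_ratio = device_ratio,
                 renyi_alpha = renyi_alpha, sampen_m = sampen_m,
                 sampen_r = sampen_r, max_gap_s = max_gap_s),
            class = "feature_config")
}

#' The feature dictionary
#'
#' Machine-readable enumeration of the 62 per-epoch features: name, unit
#' and source module. The total (43 BCG-side + 19 audio) and the sources
#' are fixed; the dictionary is versioned with the package so the count
#' is reproducible by construction.
#'
#' @return Tibble `name, unit, source, description`.
#' @export
feature_dictionary <- function() {
  f <- function(name, unit, source, description) {
    tibble(name = name, unit = unit, source = source, description = description)
  }
  bind_rows(
    f("mean_jj", "ms", "hrv_time", "mean JJ interval"),
    f("sdnn", "ms", "hrv_time", "SD of JJ intervals"),
    f("rmssd", "ms", "hrv_time", "RMS of successive JJ differences"),
    f("pnn50", "fraction", "hrv_time", "fraction |dJJ| > 50 ms"),
    f("cv_jj", "1", "hrv_time", "coefficient of variation of JJ"),
    f("lf_power", "ms^2", "hrv_freq", "LF tachogram power (0.04-0.15 Hz)"),
    f("hf_power", "ms^2", "hrv_freq", "HF tachogram power (0.15-0.40 Hz)"),
    f("lf_hf_ratio", "1", "hrv_freq", "LF/HF power ratio"),
    f("total_power", "ms^2", "hrv_freq", "total tachogram power"),
    f("lf_nu", "n.u.", "hrv_freq", "LF power, normalized units"),
    f("hf_nu", "n.u.", "hrv_freq", "HF power, normalized units"),
    f("sd1", "ms", "poincare", "Poincare width (short-term)"),
    f("sd2", "ms", "poincare", "Poincare length (long-term)"),
    f("sd1_sd2_ratio", "1", "poincare", "SD1/SD2"),
    f("porta_pct", "%", "asymmetry", "points below line of identity"),
    f("guzik_pct", "%", "asymmetry", "distance share above line of identity"),
    f("ehler_index", "1", "asymmetry", "skewness of successive differences"),
    f("phase_index", "deg", "asymmetry", "mean angular deviation, above-LOI"),
    f("area_index", "%", "asymmetry", "sector-area share above LOI"),
    f("sta_d_q1", "ms", "sta", "mean radial distance, quadrant 1 (+,+)"),
    f("sta_d_q2", "ms", "sta", "mean radial distance, quadrant 2 (-,+)"),
    f("sta_d_q3", "ms", "sta", "mean radial distance, quadrant 3 (-,-)"),
    f("sta_d_q4", "ms", "sta", "mean radial distance, quadrant 4 (+,-)"),
    f("sta_occ_q1", "fraction", "sta", "occupancy of quadrant 1"),
    f("sta_occ_q3", "fraction", "sta", "occupancy of quadrant 3"),
    f("sampen", "nats", "entropy", "sample entropy (m=2, r=0.2 SD)"),
    f("apen", "nats", "entropy", "approximate entropy (m=2, r=0.2 SD)"),
    f("dfa_alpha1", "1", "entropy", "DFA short-range exponent (4-16)"),
    f("dfa_alpha2", "1", "entropy", "DFA long-range exponent (16-64)"),
    f("renyi_h025", "bits", "entropy", "Renyi entropy, order 0.25"),
    f("renyi_h2", "bits", "entropy", "Renyi entropy, order 2"),
    f("renyi_h5", "bits", "entropy", "Renyi entropy, order 5"),
    f("rdepth", "device units", "device", "stroke-volume low-pass residual"),
    f("hrv_eq2", "device units", "device", "device HRV surrogate"),
    f("sv_mean", "device units", "device", "mean stroke volume"),
    f("bdr_mean", "breaths/min", "vitals", "mean respiration rate"),
    f("bdr_sd", "breaths/min", "vitals", "SD of respiration rate"),
    f("hr_mean", "BPM", "vitals", "mean heart rate"),
    f("hr_sd", "BPM", "vitals", "SD of heart rate"),
    f("cpc_lf", "ms^2", "cpc", "coupling index, LF band"),
    f("cpc_hf", "ms^2", "cpc", "coupling index, HF band"),
    f("cpc_ratio", "1", "cpc", "coupling LF/HF ratio"),
    f("cpc_total", "ms^2", "cpc", "coupling index, total"),
    f("aud_cp", "s", "audio", "respiration cycle period"),
    f("aud_ci", "1", "audio", "respiration cycle intensity"),
    f("aud_cc", "1", "audio", "respiration cycle consistency"),
    f("aud_if_mean", "Hz", "audio", "instantaneous frequency, mean"),
    f("aud_if_sd", "Hz", "audio", "instantaneous frequency, SD"),
    f("aud_if_median", "Hz", "audio", "instantaneous frequency, median"),
    f("aud_if_iqr", "Hz", "audio", "instantaneous frequency, IQR"),
    f("aud_energy_b1", "power", "audio", "spectral energy 0-100 Hz"),
    f("aud_energy_b2", "power", "audio", "spectral energy 100-300 Hz"),
    f("aud_energy_b3", "power", "audio", "spectral energy 300-800 Hz"),
    f("aud_energy_b4", "power", "audio", "spectral energy 800-2000 Hz"),
    f("aud_energy_b5", "power", "audio", "spectral energy 2000-8000 Hz"),
    f("aud_energy_total", "power", "audio", "total spectral energy"),
    f("aud_spl_mean", "dBFS", "audio", "sound pressure level, mean"),
    f("aud_spl_max", "dBFS", "audio", "sound pressure level, max"),
    f("aud_spl_sd", "dB", "audio", "sound pressure level, SD"),
    f("aud_spl_rms", "dBFS", "audio", "overall RMS level"),
    f("aud_breath_count", "count", "audio", "envelope breath events per epoch"),
    f("aud_lf_ratio", "fraction", "audio", "share of power below 300 Hz")
  )
}

audio_na_row <- function() {
  nms <- feature_dictionary()$name
  nms <- nms[startsWith(nms, "aud_")]
  as_tibble(setNames(as.list(rep(NA_real_, length(nms))), nms))
}

#' Assemble the per-epoch feature matrix of a session
#'
#' Runs the full feature pipeline: vitals gap interpolation, beat
#' artifact screening, 5-min sliding HRV windows (one per 30-s epoch,
#' left-truncated windows flagged `partial`), cardiopulmonary coupling
#' windows and per-epoch audio features. Deterministic given the session
#' and config. Sessions without audio get NA audio columns.
#'
#' @param session A [sleep_session()].
#' @param config A [feature_config()].
#' @return A tibble of class `feature_matrix`: `epoch`, `partial`, then
#'   the 62 feature columns of [feature_dictionary()].
#' @export
assemble_features <- function(session, config = feature_config()) {
  stopifnot(inherits(session, "sleep_session"))
  filled <- fill_gaps(session$vitals, max_gap_s = config$max_gap_s)
  vit <- filled$vitals
  bmask <- mask_artifacts(session$beats, config$artifact_lo_ms,
                          config$artifact_hi_ms, config$artifact_jump_frac)
  beats <- bmask[bmask$valid, c("t", "jj_ms")]
  wins <- sliding_windows(session, length_s = config$window_s)

  hrv_rows <- map(seq_len(nrow(wins)), function(i) {
    w <- wins[i, ]
    sel <- beats$t >= w$start_s & beats$t < w$end_s
    jj <- beats$jj_ms[sel]
    tt <- beats$t[sel]
    vsel <- vit$t >= w$start_s & vit$t < w$end_s
    td <- hrv_time_domain(jj)
    fd <- hrv_freq_domain(tt, jj, lf_band = config$lf_band,
                          hf_band = config$hf_band)
    ps <- poincare_sd(jj)
    as <- poincare_asymmetry(jj)
    st <- sta_features(jj)
    en <- sample_approx_entropy(jj, m = config$sampen_m, r_frac = config$sampen_r)
    df_ <- dfa(jj)
    ry <- renyi_entropy(jj, alpha = config$renyi_alpha)
    sv <- vit$sv[vsel]
    dv <- device_hrv(sv, fd$lf_power, fd$hf_power, k = config$sv_k,
                     ratio = config$device_ratio)
    bdr <- vit$bdr[vsel]; hr <- vit$hr[vsel]
    tibble(
      epoch = w$epoch, partial = w$partial,
      mean_jj = td$mean_jj, sdnn = td$sdnn, rmssd = td$rmssd,
      pnn50 = td$pnn50, cv_jj = td$cv_jj,
      lf_power = fd$lf_power, hf_power = fd$hf_power,
      lf_hf_ratio = fd$lf_hf_ratio, total_power = fd$total_power,
      lf_nu = fd$lf_nu, hf_nu = fd$hf_nu,
      sd1 = ps$sd1, sd2 = ps$sd2, sd1_sd2_ratio = ps$sd1_sd2_ratio,
      porta_pct = as$porta_pct, guzik_pct = as$guzik_pct,
      ehler_index = as$ehler_index, phase_index = as$phase_index,
      area_index = as$area_index,
      sta_d_q1 = st$sta_d_q1, sta_d_q2 = st$sta_d_q2,
      sta_d_q3 = st$sta_d_q3, sta_d_q4 = st$sta_d_q4,
      sta_occ_q1 = st$sta_occ_q1, sta_occ_q3 = st$sta_occ_q3,
      sampen = ifelse(is.finite(en$sampen), en$sampen, NA_real_),
      apen = en$apen,
      dfa_alpha1 = df_$dfa_alpha1, dfa_alpha2 = df_$dfa_alpha2,
      renyi_h025 = ry$h_bits[1], renyi_h2 = ry$h_bits[2],
      renyi_h5 = ry$h_bits[3],
      rdepth = dv$rdepth, hrv_eq2 = dv$hrv_eq2,
      sv_mean = if (any(is.finite(sv))) mean(sv, na.rm = TRUE) else NA_real_,
      bdr_mean = if (any(is.finite(bdr))) mean(bdr, na.rm = TRUE) else NA_real_,
      bdr_sd = if (sum(is.finite(bdr)) > 1) sd(bdr, na.rm = TRUE) else NA_real_,
      hr_mean = if (any(is.finite(hr))) mean(hr, na.rm = TRUE) else NA_real_,
      hr_sd = if (sum(is.finite(hr)) > 1) sd(hr, na.rm = TRUE) else NA_real_
    )
  })
  out <- bind_rows(hrv_rows)

  cpc <- tryCatch(
    cpc_series(sleep_session(session$subject_id, session$session_id,
                             beat_series(beats$t, beats$jj_ms), vit,
                             audio = NULL, hypnogram = NULL),
               lf_band = config$cpc_lf_band, hf_band = config$cpc_hf_band),
    error = function(e) tibble(epoch = out$epoch, cpc_lf = NA_real_,
                               cpc_hf = NA_real_, cpc_ratio = NA_real_,
                               cpc_total = NA_real_)
  )
  out <- left_join(out, select(cpc, "epoch", "cpc_lf", "cpc_hf",
                               "cpc_ratio", "cpc_total"), by = "epoch")

  if (!is.null(session$audio)) {
    sr <- session$audio$sample_rate
    aud_rows <- map(out$epoch, function(ep) {
      i0 <- round(ep * EPOCH_S * sr) + 1L
      i1 <- min(round((ep + 1) * EPOCH_S * sr), length(session$audio$samples))
      if (i1 - i0 + 1 < AUDIO_NFFT) return(audio_na_row())
      seg <- audio_recording(session$audio$samples[i0:i1], sr)
      ac <- acoustic_stats(seg)
      env <- respiration_envelope(seg)
      resp <- if (var(env$env) > 0) {
        respiration_cycle_features(
          autocorrelation_rk(env$env, lag_max = length(env$env) - 1L),
          frame_rate = env$frame_rate)
      } else tibble(cp = NA_real_, ci = NA_real_, cc = NA_real_, detected = FALSE)
      tibble(aud_cp = resp$cp, aud_ci = resp$ci, aud_cc = resp$cc,
             aud_if_mean = ac$instfreq_mean, aud_if_sd = ac$instfreq_sd,
             aud_if_median = ac$instfreq_median, aud_if_iqr = ac$instfreq_iqr,
             aud_energy_b1 = ac$energy_b1, aud_energy_b2 = ac$energy_b2,
             aud_energy_b3 = ac$energy_b3, aud_energy_b4 = ac$energy_b4,
             aud_energy_b5 = ac$energy_b5, aud_energy_total = ac$energy_total,
             aud_spl_mean = ac$spl_mean, aud_spl_max = ac$spl_max,
             aud_spl_sd = ac$spl_sd, aud_spl_rms = ac$spl_rms,
             aud_breath_count = as.numeric(ac$breath_count),
             aud_lf_ratio = ac$lf_power_ratio)
    })
    out <- dplyr::bind_cols(out, bind_rows(aud_rows))
  } else {
    warn("session has no audio; audio features flagged missing")
    out <- dplyr::bind_cols(out, audio_na_row()[rep(1, nrow(out)), ])
  }
  class(out) <- c("feature_matrix", class(out))
  out
}

#' Feature column names of a feature matrix
#' @param matrix A `feature_matrix` tibble.
#' @return Character vector of the 62 feature column names.
#' @export
feature_columns <- function(matrix) {
  intersect(feature_dictionary()$name, names(matrix))
}

#' Z-score features with training-fold statistics
#'
#' Normalization constants (per-column mean and SD) are computed from the
#' training matrices only and applied unchanged to held-out data, so no
#' statistic ever leaks across the subject split. Zero-variance columns
#' are left unscaled with a warning.
#'
#' @param train List of `feature_matrix` tibbles (the training fold).
#' @param apply_to Optional list of matrices to transform with the
#'   training constants (defaults to `train`).
#' @return List with `matrices` (transformed `apply_to`), `center`,
#'   `scale`.
#' @export
normalize_features <- function(train, apply_to = NULL) {
  if (inherits(train, "feature_matrix")) train <- list(train)
  if (is.null(apply_to)) apply_to <- train
  if (inherits(apply_to, "feature_matrix")) apply_to <- list(apply_to)
  cols <- feature_columns(train[[1]])
  stacked <- bind_rows(map(train, ~ .x[, cols]))
  center <- map_dbl(stacked, ~ mean(.x, na.rm = TRUE))
  scale_ <- map_dbl(stacked, ~ sd(.x, na.rm = TRUE))
  degenerate <- !is.finite(scale_) | scale_ == 0
  if (any(degenerate)) {
    warn(sprintf("zero-variance column(s) left unscaled: %s",
                 paste(cols[degenerate], collapse = ", ")))
    scale_[degenerate] <- 1
    center[degenerate & !is.finite(center)] <- 0
  }
  center[!is.finite(center)] <- 0
  out <- map(apply_to, function(m) {
    for (j in seq_along(cols)) {
      m[[cols[j]]] <- (m[[cols[j]]] - center[j]) / scale_[j]
    }
    m
  })
  list(matrices = out, center = center, scale = scale_)
}

#' Impute masked feature cells
#'
#' Applied only at model-input time. `carry-forward` uses the previous
#' epoch's value, falling back to the column median for leading gaps;
#' `column-median` uses the per-column median; `none` returns the matrix
#' unchanged. The NA pattern prior to imputation is recorded in the
#' `imputed` attribute for audit.
#'
#' @param matrix A `feature_matrix` tibble.
#' @param policy One of `"carry-forward"`, `"column-median"`, `"none"`.
#' @return The imputed matrix.
#' @export
impute_features <- function(matrix, policy = c("carry-forward", "column-median", "none")) {
  policy <- match.arg(policy)
  if (policy == "none") return(matrix)
  cols <- feature_columns(matrix)
  was_na <- is.na(matrix[, cols])
  for (cl in cols) {
    v <- matrix[[cl]]
    med <- median(v, na.rm = TRUE)
    if (!is.finite(med)) med <- 0
    if (policy == "column-median") {
      v[is.na(v)] <- med
    } else {
      for (i in seq_along(v)) {
        if (is.na(v[i])) v[i] <- if (i > 1) v[i - 1] else med
      }
    }
    matrix[[cl]] <- v
  }
  attr(matrix, "imputed") <- was_na
  matrix
}
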