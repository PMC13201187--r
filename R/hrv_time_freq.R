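# Time- and frequency-domain HRV over 5-min windows, plus the bed
# sensor's own stroke-volume-based HRV surrogate.

#' Time-domain HRV features
#'
#' Classical short-term statistics of the JJ-interval series: mean
#' interval, SDNN (sample SD), RMSSD (root-mean-square of successive
#' differences), pNN50 (fraction of successive differences exceeding
#' 50 ms) and the coefficient of variation.
#'
#' @param jj Numeric vector of valid JJ intervals (ms).
#' @return Tibble with `mean_jj, sdnn, rmssd, pnn50, cv_jj` (one row);
#'   all-NA with `ok = FALSE` when fewer than 2 intervals are available.
#' @export
hrv_time_domain <- function(jj) {
  jj <- jj[is.finite(jj)]
  if (length(jj) < 2) {
    return(tibble(mean_jj = NA_real_, sdnn = NA_real_, rmssd = NA_real_,
                  pnn50 = NA_real_, cv_jj = NA_real_, ok = FALSE))
  }
  d <- diff(jj)
  tibble(mean_jj = mean(jj), sdnn = sd(jj), rmssd = sqrt(mean(d^2)),
         pnn50 = mean(abs(d) > 50), cv_jj = sd(jj) / mean(jj), ok = TRUE)
}

#' Frequency-domain HRV features
#'
#' Band powers of the beat-interval tachogram. The irregularly sampled
#' series is cubic-spline resampled to `resample_hz`, linearly detrended,
#' and its PSD estimated by Welch's method (Hann segments of
#' `seg_s` seconds, 50% overlap). Powers are integrated over the LF and
#' HF bands; `lf_nu + hf_nu = 1` whenever `lf + hf > 0`.
#'
#' @param t,jj Beat onset times (s) and JJ intervals (ms) of the window.
#' @param lf_band,hf_band Band edges in Hz (defaults 0.04-0.15 and
#'   0.15-0.40, the conventional short-term HRV bands).
#' @param resample_hz Tachogram resampling rate (default 4).
#' @param seg_s Welch segment length in seconds (default 120).
#' @return Tibble `lf_power, hf_power, lf_hf_ratio, total_power, lf_nu,
#'   hf_nu, ok` (powers in ms^2).
#' @export
hrv_freq_domain <- function(t, jj, lf_band = c(0.04, 0.15),
                            hf_band = c(0.15, 0.40),
                            resample_hz = 4, seg_s = 120) {
  ok_idx <- is.finite(t) & is.finite(jj)
  t <- t[ok_idx]; jj <- jj[ok_idx]
  empty <- tibble(lf_power = NA_real_, hf_power = NA_real_,
                  lf_hf_ratio = NA_real_, total_power = NA_real_,
                  lf_nu = NA_real_, hf_nu = NA_real_, ok = FALSE)
  if (length(t) < 4 || (t[length(t)] - t[1]) < 120) return(empty)
  tach <- resample_uniform(t, jj, resample_hz)
  nseg <- min(length(tach$x), seg_s * resample_hz)
  psd <- welch_psd(detrend_linear(tach$x), resample_hz, nseg = nseg)
  lf <- band_power(psd$freq, psd$psd, lf_band[1], lf_band[2])
  hf <- band_power(psd$freq, psd$psd, hf_band[1], hf_band[2])
  tot <- band_power(psd$freq, psd$psd, 0.003, hf_band[2])
  denom <- lf + hf
  tibble(lf_power = lf, hf_power = hf,
         lf_hf_ratio = if (hf > 0) lf / hf else NA_real_,
         total_power = tot,
         lf_nu = if (denom > 0) lf / denom else NA_real_,
         hf_nu = if (denom > 0) hf / denom else NA_real_,
         ok = TRUE)
}

#' Device-style stroke-volume HRV surrogate
#'
#' Reproduces the bed sensor's processed HRV output: respiration depth
#' (R-depth) is the mean absolute residual of the stroke-volume signal
#' about its exponential low-pass (constant `k`), and the HRV surrogate
#' multiplies it by the HF/LF tachogram power ratio. The conventional
#' LF/HF orientation and an SV-normalized R-depth are available as
#' switches.
#'
#' @param sv Stroke-volume samples of the window (device units).
#' @param lf,hf LF and HF tachogram band powers for the same window.
#' @param k Low-pass filter constant (default 0.1).
#' @param ratio One of `"hf_lf"` (default, as the device defines it) or
#'   `"lf_hf"`.
#' @param normalize_sv If TRUE, divide the residual by the smoothed SV
#'   before averaging.
#' @return Tibble `rdepth, hrv_eq2, ok`.
#' @export
device_hrv <- function(sv, lf, hf, k = 0.1, ratio = c("hf_lf", "lf_hf"),
                       normalize_sv = FALSE) {
  ratio <- match.arg(ratio)
  sv <- sv[is.finite(sv)]
  if (!length(sv)) {
    return(tibble(rdepth = NA_real_, hrv_eq2 = NA_real_, ok = FALSE))
  }
  smooth <- lowpass_smooth(sv, k)
  resid <- abs(sv - smooth)
  if (normalize_sv) resid <- resid / pmax(abs(smooth), .Machine$double.eps)
  rdepth <- mean(resid)
  r <- if (ratio == "hf_lf") {
    if (is.finite(lf) && lf > 0) hf / lf else NA_real_
  } else {
    if (is.finite(hf) && hf > 0) lf / hf else NA_real_
  }
  tibble(rdepth = rdepth, hrv_eq2 = r * rdepth,
         ok = is.finite(r * rdepth))
}
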