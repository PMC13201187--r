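# Cardiopulmonary coupling: cross-spectral power and magnitude-squared
# coherence between the beat-interval tachogram and the BCG-derived
# respiration signal, combined into a per-frequency coupling index.

CPC_FS <- 2          # Hz, analysis rate of both signals
CPC_WINDOW <- 1024L  # samples per analysis window (512 s at 2 Hz)
CPC_SUB <- 512L      # sub-window length
CPC_SUB_STEP <- 256L # sub-window offsets 0, 256, 512

#' Cardiopulmonary coupling spectrum of one window
#'
#' Both inputs are 1024-sample segments at 2 Hz on the same time support.
#' Each is split into three 512-sample sub-windows (offsets 0, 256, 512),
#' linearly detrended and Hann-windowed before the Fourier transform.
#' Cross- and auto-spectra are averaged across the sub-windows; the
#' magnitude-squared coherence is
#' `C_xy(f) = |P_xy(f)|^2 / (P_xx(f) P_yy(f))` of the averaged spectra,
#' and the coupling index is the per-frequency product
#' `cpc(f) = |P_xy(f)|^2 * C_xy(f)`. Sub-window averaging is what makes
#' the coherence informative: a single segment gives identically 1.
#'
#' @param x,y Numeric segments of exactly 1024 samples at 2 Hz
#'   (tachogram and respiration, order irrelevant for the magnitudes).
#' @param product_order `"per_frequency"` (default: multiply, then
#'   integrate over bands) or `"band_average"` (average the cross power
#'   over the band before multiplying by the band-mean coherence).
#' @return Tibble of class `cpc_spectrum`: `freq, cross_power, coherence,
#'   cpc`, with attribute `product_order`; all-zero power with coherence
#'   reported 0 for constant segments.
#' @export
cpc_window <- function(x, y, product_order = c("per_frequency", "band_average")) {
  product_order <- match.arg(product_order)
  if (length(x) != CPC_WINDOW || length(y) != CPC_WINDOW) {
    abort(sprintf("cpc_window needs exactly %d samples per signal", CPC_WINDOW),
          class = "bcgsleep_parameter_error")
  }
  w <- hann_window(CPC_SUB)
  scale <- CPC_FS * sum(w^2)
  offsets <- seq(0L, CPC_WINDOW - CPC_SUB, by = CPC_SUB_STEP)
  n_half <- CPC_SUB / 2 + 1L
  pxx <- pyy <- numeric(n_half)
  pxy <- complex(real = numeric(n_half), imaginary = numeric(n_half))
  for (o in offsets) {
    idx <- (o + 1L):(o + CPC_SUB)
    X <- fft(detrend_linear(x[idx]) * w)[seq_len(n_half)]
    Y <- fft(detrend_linear(y[idx]) * w)[seq_len(n_half)]
    pxx <- pxx + Mod(X)^2 / scale
    pyy <- pyy + Mod(Y)^2 / scale
    pxy <- pxy + X * Conj(Y) / scale
  }
  k <- length(offsets)
  pxx <- pxx / k; pyy <- pyy / k; pxy <- pxy / k
  denom <- pxx * pyy
  # a numerically zero-power signal (constant segment) has no defined
  # coherence; report 0 rather than a detrend-residual artifact
  coh <- ifelse(denom > 1e-20, Mod(pxy)^2 / denom, 0)
  coh <- pmin(pmax(coh, 0), 1)
  cross <- Mod(pxy)^2
  out <- tibble(freq = (seq_len(n_half) - 1) * CPC_FS / CPC_SUB,
                cross_power = cross, coherence = coh, cpc = cross * coh)
  attr(out, "product_order") <- product_order
  class(out) <- c("cpc_spectrum", class(out))
  out
}

cpc_band_features <- function(spec, lf_band = c(0.01, 0.10),
                              hf_band = c(0.10, 0.40)) {
  order <- attr(spec, "product_order") %||% "per_frequency"
  if (order == "per_frequency") {
    lf <- band_power(spec$freq, spec$cpc, lf_band[1], lf_band[2])
    hf <- band_power(spec$freq, spec$cpc, hf_band[1], hf_band[2])
    tot <- band_power(spec$freq, spec$cpc, lf_band[1], hf_band[2])
  } else {
    band_val <- function(lo, hi) {
      sel <- spec$freq >= lo & spec$freq < hi
      if (!any(sel)) return(0)
      mean(spec$cross_power[sel]) * mean(spec$coherence[sel])
    }
    lf <- band_val(lf_band[1], lf_band[2])
    hf <- band_val(hf_band[1], hf_band[2])
    tot <- band_val(lf_band[1], hf_band[2])
  }
  tibble(cpc_lf = lf, cpc_hf = hf,
         cpc_ratio = if (hf > 0) lf / hf else NA_real_,
         cpc_total = tot)
}

#' Per-epoch cardiopulmonary coupling features
#'
#' Resamples the JJ tachogram and the zero-meaned 1 Hz respiration (BDR)
#' series to 2 Hz by cubic splines, then slides a 1024-sample (512 s)
#' window in 30-s steps across the session, one window per epoch,
#' right-aligned to the epoch's end. Epochs ending before 512 s reuse the
#' first full window and are flagged `partial`. Each window's coupling
#' spectrum is reduced to LF/HF band features.
#'
#' @param session A [sleep_session()] (vitals gaps should be filled
#'   first; see [fill_gaps()]).
#' @param lf_band,hf_band Coupling band edges in Hz (defaults 0.01-0.10
#'   and 0.10-0.40).
#' @param product_order Passed to [cpc_window()].
#' @return Tibble `epoch, cpc_lf, cpc_hf, cpc_ratio, cpc_total, partial`.
#' @export
cpc_series <- function(session, lf_band = c(0.01, 0.10),
                       hf_band = c(0.10, 0.40),
                       product_order = "per_frequency") {
  stopifnot(inherits(session, "sleep_session"))
  if (session$duration_s < CPC_WINDOW / CPC_FS) {
    abort(sprintf("session shorter than one %d-s coupling window",
                  CPC_WINDOW / CPC_FS),
          class = "bcgsleep_parameter_error")
  }
  tach <- resample_uniform(session$beats$t, session$beats$jj_ms, CPC_FS)
  bdr <- session$vitals$bdr
  bdr[!is.finite(bdr)] <- mean(bdr, na.rm = TRUE)
  resp <- resample_uniform(session$vitals$t, bdr - mean(bdr), CPC_FS)
  t0 <- max(tach$t[1], resp$t[1])
  t_end <- min(tach$t[nrow(tach)], resp$t[nrow(resp)])
  g <- epoch_grid(session)
  win_s <- CPC_WINDOW / CPC_FS
  rows <- map(g$epoch, function(ep) {
    end <- (ep + 1) * EPOCH_S
    start <- end - win_s
    partial <- start < t0
    if (partial) { start <- t0; end <- t0 + win_s }
    if (end > t_end + 1 / CPC_FS) { end <- t_end; start <- end - win_s }
    xi <- round((start - tach$t[1]) * CPC_FS) + 1L
    yi <- round((start - resp$t[1]) * CPC_FS) + 1L
    x <- tach$x[xi:(xi + CPC_WINDOW - 1L)]
    y <- resp$x[yi:(yi + CPC_WINDOW - 1L)]
    if (anyNA(x) || anyNA(y)) {
      return(tibble(epoch = ep, cpc_lf = NA_real_, cpc_hf = NA_real_,
                    cpc_ratio = NA_real_, cpc_total = NA_real_,
                    partial = partial))
    }
    spec <- cpc_window(x, y, product_order = product_order)
    mutate(cpc_band_features(spec, lf_band, hf_band),
           epoch = ep, partial = partial, .before = 1)
  })
  bind_rows(rows)
}
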