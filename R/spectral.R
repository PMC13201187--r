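# Shared spectral helpers: Hann-windowed segment FFTs, Welch PSD and a
# short-time Fourier transform with overlap-add inverse. All estimators
# are one-sided and density-scaled (power per Hz) unless noted.

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)

detrend_linear <- function(x) {
  n <- length(x)
  if (n < 2) return(x - mean(x))
  i <- seq_len(n)
  stats::lm.fit(cbind(1, i), x)$residuals
}

# Segment starts for length-n signal, segment nseg, overlap fraction.
segment_starts <- function(n, nseg, overlap = 0.5) {
  hop <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = hop)
  starts
}

#' Welch power spectral density
#'
#' Averaged modified periodograms: linear detrend and Hann window per
#' segment, one-sided density scaling (`sum(psd) * df` approximates the
#' signal variance).
#'
#' @param x Uniformly sampled signal.
#' @param fs Sampling rate (Hz).
#' @param nseg Segment length in samples (default: `min(length(x), 256)`).
#' @param overlap Overlap fraction between segments (default 0.5).
#' @param demean Subtract the segment mean/trend first (default TRUE).
#' @return Tibble `freq, psd`.
#' @export
welch_psd <- function(x, fs, nseg = min(length(x), 256L), overlap = 0.5,
                      demean = TRUE) {
  n <- length(x)
  nseg <- min(nseg, n)
  w <- hann_window(nseg)
  scale <- fs * sum(w^2)
  starts <- segment_starts(n, nseg, overlap)
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    if (demean) seg <- detrend_linear(seg)
    X <- fft(seg * w)
    acc <- acc + Mod(X)^2 / scale
  }
  p <- acc / length(starts)
  n_half <- floor(nseg / 2) + 1L
  p <- p[seq_len(n_half)]
  # one-sided: double everything except DC (and Nyquist when nseg even)
  dbl <- rep(2, n_half); dbl[1] <- 1
  if (nseg %% 2 == 0) dbl[n_half] <- 1
  tibble(freq = (seq_len(n_half) - 1) * fs / nseg, psd = p * dbl)
}

band_power <- function(freq, psd, lo, hi) {
  sel <- freq >= lo & freq < hi
  if (!any(sel)) return(0)
  df <- if (length(freq) > 1) freq[2] - freq[1] else 1
  sum(psd[sel]) * df
}

# STFT: returns complex matrix (frames x bins, full spectrum) plus frame
# times; hop = nfft - noverlap samples.
stft_frames <- function(x, nfft, hop, window = hann_window(nfft)) {
  n <- length(x)
  if (n < nfft) abort("segment shorter than one analysis frame",
                      class = "bcgsleep_parameter_error")
  starts <- seq(1L, n - nfft + 1L, by = hop)
  spec <- matrix(0 + 0i, nrow = length(starts), ncol = nfft)
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + nfft - 1L)]
    spec[i, ] <- fft(seg * window)
  }
  list(spec = spec, starts = starts)
}

# Inverse STFT by overlap-add; assumes the analysis used a Hann window
# with 50% overlap (COLA-compliant up to a constant).
istft_overlap_add <- function(spec, starts, nfft, n_out,
                              window = hann_window(nfft)) {
  y <- numeric(n_out)
  wsum <- numeric(n_out)
  for (i in seq_along(starts)) {
    seg <- Re(fft(spec[i, ], inverse = TRUE)) / nfft
    idx <- starts[i]:(starts[i] + nfft - 1L)
    keep <- idx <= n_out
    y[idx[keep]] <- y[idx[keep]] + seg[keep] * window[keep]
    wsum[idx[keep]] <- wsum[idx[keep]] + window[keep]^2
  }
  nz <- wsum > 1e-12
  y[nz] <- y[nz] / wsum[nz]
  y
}
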