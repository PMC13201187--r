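# Stream conditioning: exponential smoothing, gap interpolation, beat
# artifact screening, sliding analysis windows and uniform resampling.

#' Exponential low-pass smoothing
#'
#' First-order recursive filter `y(t) = (1 - k) * y(t-1) + k * x(t)` with
#' `y(-1) = y0`. `k = 1` is the identity; smaller `k` smooths harder. The
#' output is a convex combination of past inputs, so it stays inside
#' `[min(x, y0), max(x, y0)]`.
#'
#' @param x Numeric sample sequence.
#' @param k Filter constant in `(0, 1]`.
#' @param y0 Initial state (default: first sample).
#' @return Numeric vector, same length as `x`.
#' @export
lowpass_smooth <- function(x, k, y0 = x[1]) {
  if (!(is.numeric(k) && length(k) == 1 && k > 0 && k <= 1)) {
    abort("filter constant k must lie in (0, 1]", class = "bcgsleep_parameter_error")
  }
  if (!length(x)) return(numeric(0))
  if (any(!is.finite(x))) abort("samples must be finite", class = "bcgsleep_parameter_error")
  # y_t = (1-k) y_{t-1} + k x_t  ==  filter() with AR coefficient (1-k)
  as.numeric(stats::filter(k * x, filter = 1 - k, method = "recursive",
                           init = y0))
}

#' Interpolate short gaps in a 1 Hz vitals series
#'
#' Missing seconds (absent rows or NA values) are filled by linear
#' interpolation when the surrounding gap is at most `max_gap_s`; longer
#' gaps are left missing and masked invalid. Originally present samples
#' are never altered.
#'
#' @param vitals A [vitals_series()] (possibly with missing rows/NAs).
#' @param max_gap_s Longest gap (s) that is still interpolated.
#' @return A list with `vitals` (uniform 1 Hz grid) and `mask` (tibble
#'   `t, valid, reason` where reason is `""`, `"interpolated"` or
#'   `"dropout"`).
#' @export
fill_gaps <- function(vitals, max_gap_s = 30) {
  stopifnot(inherits(vitals, "vitals_series"))
  if (is.unsorted(vitals$t)) abort("timestamps must be sorted")
  t_grid <- seq(floor(min(vitals$t)), ceiling(max(vitals$t)))
  fill_one <- function(v) {
    present_t <- vitals$t[!is.na(v)]
    present_v <- v[!is.na(v)]
    out <- rep(NA_real_, length(t_grid))
    idx <- match(round(present_t), t_grid)
    out[idx] <- present_v
    reason <- rep("", length(t_grid))
    miss <- which(is.na(out))
    if (length(miss) && length(present_t) >= 2) {
      runs <- split(miss, cumsum(c(1, diff(miss) != 1)))
      interp <- approx(present_t, present_v, xout = t_grid, rule = 1)$y
      for (r in runs) {
        lo <- if (min(r) > 1) t_grid[min(r) - 1] else -Inf
        hi <- if (max(r) < length(t_grid)) t_grid[max(r) + 1] else Inf
        gap <- hi - lo
        if (is.finite(gap) && gap <= max_gap_s) {
          out[r] <- interp[r]
          reason[r] <- "interpolated"
        } else {
          reason[r] <- "dropout"
        }
      }
    } else if (length(miss)) {
      reason[miss] <- "dropout"
    }
    list(v = out, reason = reason)
  }
  hr <- fill_one(vitals$hr); bdr <- fill_one(vitals$bdr)
  sv <- fill_one(vitals$sv); hrv <- fill_one(vitals$hrv)
  reason <- hr$reason
  reason[reason == "" & bdr$reason != ""] <- bdr$reason[reason == "" & bdr$reason != ""]
  reason[reason == "" & sv$reason != ""] <- sv$reason[reason == "" & sv$reason != ""]
  filled <- vitals_series(t_grid, hr$v, bdr$v, sv$v, hrv$v)
  mask <- tibble(t = t_grid, valid = reason != "dropout", reason = reason)
  list(vitals = filled, mask = mask)
}

#' Screen beat intervals for artifacts
#'
#' Flags physiologically implausible beats (outside `[lo_ms, hi_ms]`,
#' default 300-2000 ms, i.e. 30-200 BPM) and motion/ectopy suspects whose
#' interval differs from the previous *valid* beat by more than
#' `jump_frac`. Masked beats are removed (not interpolated) before any
#' HRV computation, because interpolating intervals distorts variability.
#'
#' @param beats A [beat_series()].
#' @param lo_ms,hi_ms Valid interval range in ms.
#' @param jump_frac Maximum fractional jump vs the previous valid beat.
#' @return Tibble `t, jj_ms, valid, reason`.
#' @export
mask_artifacts <- function(beats, lo_ms = 300, hi_ms = 2000, jump_frac = 0.3) {
  stopifnot(inherits(beats, "beat_series"))
  if (!(lo_ms > 0 && hi_ms > lo_ms && jump_frac > 0)) {
    abort("need 0 < lo_ms < hi_ms and jump_frac > 0", class = "bcgsleep_parameter_error")
  }
  n <- nrow(beats)
  valid <- rep(TRUE, n)
  reason <- rep("", n)
  out_of_range <- beats$jj_ms < lo_ms | beats$jj_ms > hi_ms
  valid[out_of_range] <- FALSE
  reason[out_of_range] <- "physiologic-range"
  prev <- NA_real_
  for (i in seq_len(n)) {
    if (!valid[i]) next
    if (!is.na(prev) && abs(beats$jj_ms[i] - prev) / prev > jump_frac) {
      valid[i] <- FALSE
      reason[i] <- "movement-burst"
    } else {
      prev <- beats$jj_ms[i]
    }
  }
  tibble(t = beats$t, jj_ms = beats$jj_ms, valid = valid, reason = reason)
}

#' Per-epoch sliding analysis windows
#'
#' One 5-min window per 30-s epoch: each window is the 300 s ending at
#' that epoch's end, left-truncated at the session start (and flagged
#' `partial`) for the first nine epochs, so that every epoch owns exactly
#' one feature row.
#'
#' @param session A [sleep_session()].
#' @param length_s Window length in seconds (default 300).
#' @param step_s Window step, equal to the epoch pitch (default 30).
#' @return Tibble `epoch, start_s, end_s, partial`.
#' @export
sliding_windows <- function(session, length_s = 300, step_s = 30) {
  stopifnot(inherits(session, "sleep_session"))
  if (length_s %% step_s != 0 || length_s <= 0 || step_s <= 0) {
    abort("step must divide length and both must be positive",
          class = "bcgsleep_parameter_error")
  }
  g <- epoch_grid(session)
  start <- pmax(0, g$end_s - length_s)
  tibble(epoch = g$epoch, start_s = start, end_s = g$end_s,
         partial = g$end_s - start < length_s)
}

#' Resample a nonuniform series onto a uniform grid
#'
#' Cubic-spline interpolation onto a uniform grid at `target_hz`, spanning
#' the support of the input. The interpolant passes through the original
#' samples exactly.
#'
#' @param t,x Sample times (sorted) and values.
#' @param target_hz Target rate in Hz.
#' @return Tibble `t, x` on the uniform grid.
#' @export
resample_uniform <- function(t, x, target_hz) {
  if (length(t) < 4) {
    abort("need at least 4 points for cubic interpolation",
          class = "bcgsleep_parameter_error")
  }
  if (is.unsorted(t)) abort("series must be sorted", class = "bcgsleep_parameter_error")
  grid <- seq(t[1], t[length(t)], by = 1 / target_hz)
  fit <- spline(t, x, xout = grid, method = "fmm")
  tibble(t = fit$x, x = fit$y)
}
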