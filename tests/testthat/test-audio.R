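tone <- function(freq, dur = 2, sr = 8000, amp = 0.5) {
  audio_recording(amp * sin(2 * pi * freq * seq(0, dur, by = 1 / sr)), sr)
}

test_that("spectrogram frame count and peak bin are as specified", {
  sr <- 44100
  a <- audio_recording(sin(2 * pi * 1000 * seq_len(30 * sr) / sr), sr)
  spec <- audio_spectrogram(a)
  expect_equal(nrow(spec$power), floor((30 * sr - 2048) / 1024) + 1)
  peak_bins <- apply(spec$power, 1, which.max)
  expect_true(all(abs(spec$freq[peak_bins] - 1000) < sr / 2048))

  silent <- audio_recording(numeric(5000), 8000)
  expect_true(all(audio_spectrogram(silent)$power < 1e-20))
})

test_that("instantaneous frequency is the power-weighted centroid", {
  a <- tone(440, dur = 2)
  fi <- instantaneous_frequency(audio_spectrogram(a))
  expect_true(all(abs(fi - 440) < 8000 / 2048))

  sr <- 8000
  t <- seq(0, 2, by = 1 / sr)
  two <- audio_recording(sin(2 * pi * 200 * t) + sin(2 * pi * 600 * t), sr)
  fi2 <- instantaneous_frequency(audio_spectrogram(two))
  expect_equal(mean(fi2), 400, tolerance = 10)

  # linear chirp: centroid increases monotonically (smoothed check)
  chirp <- audio_recording(sin(2 * pi * (200 * t + 200 * t^2 / 2)), sr)
  fi3 <- instantaneous_frequency(audio_spectrogram(chirp))
  expect_gt(mean(diff(fi3) > 0), 0.9)
  expect_gt(fi3[length(fi3)], fi3[1] + 200)
})

test_that("centroid stays inside the powered support per frame", {
  set.seed(32)
  a <- audio_recording(rnorm(20000), 8000)
  spec <- audio_spectrogram(a)
  fi <- instantaneous_frequency(spec)
  for (i in seq_along(fi)) {
    powered <- spec$freq[spec$power[i, ] > 0]
    expect_gte(fi[i], min(powered))
    expect_lte(fi[i], max(powered))
  }
})

test_that("autocorrelation matches the literal definition and is bounded", {
  set.seed(33)
  y <- rnorm(10)
  r <- autocorrelation_rk(y)
  expect_equal(r$r[1], 1)
  for (k in 0:6) {
    expect_equal(r$r[r$lag == k], bf_autocorr(y, k), tolerance = 1e-12)
  }
  y2 <- rnorm(200)
  r2 <- autocorrelation_rk(y2)
  expect_true(all(abs(r2$r) <= 1 + 1e-12))

  # periodic envelope: local autocorrelation maximum at the period
  period <- 25
  saw <- rep(seq(0, 1, length.out = period), 12)
  r3 <- autocorrelation_rk(saw, lag_max = 60)
  expect_equal(r3$lag[which.max(r3$r[r3$lag >= 10])] + 9, period - 1,
               tolerance = 2)

  expect_true(all(is.na(autocorrelation_rk(rep(1, 50))$r)))
})

test_that("respiration cycle features recover a constructed breath period", {
  fr <- 8000 / 1024
  lag <- 0:120
  r <- tibble::tibble(lag = lag, r = cos(2 * pi * lag / (4 * fr)) *
                        exp(-lag / 200))
  out <- respiration_cycle_features(r, frame_rate = fr)
  expect_true(out$detected)
  expect_equal(out$cp, 4, tolerance = 0.25)
  expect_gt(out$ci, 0.5)

  # equal-amplitude peaks: consistency 0
  r2 <- tibble::tibble(lag = 0:100, r = cos(2 * pi * (0:100) / 30) * 0.8)
  r2$r[1] <- 1
  out2 <- respiration_cycle_features(r2, frame_rate = fr)
  expect_equal(out2$cc, 0, tolerance = 1e-9)

  # white-noise envelopes rarely pass the prominence threshold
  set.seed(34)
  det <- replicate(40, {
    env <- rnorm(230)
    respiration_cycle_features(autocorrelation_rk(env), frame_rate = fr)$detected
  })
  expect_lt(mean(det), 0.3)
})

test_that("closed loop: synthetic breathing audio yields its breath period", {
  set.seed(35)
  sr <- 8000
  dur <- 30
  n <- dur * sr
  t0 <- 0; x <- 0.003 * rnorm(n)
  while (t0 < dur - 2) {
    i0 <- floor(t0 * sr) + 1
    i1 <- min(i0 + 1.8 * sr, n)
    idx <- i0:i1
    x[idx] <- x[idx] + 0.2 * sin(pi * seq_along(idx) / length(idx))^2 * rnorm(length(idx))
    t0 <- t0 + 4
  }
  a <- audio_recording(x, sr)
  env <- bcgsleep:::respiration_envelope(a)
  out <- respiration_cycle_features(
    autocorrelation_rk(env$env), frame_rate = env$frame_rate)
  expect_true(out$detected)
  expect_equal(out$cp, 4, tolerance = 0.4)
})

test_that("acoustic statistics transform correctly under amplitude scaling", {
  set.seed(36)
  x <- rnorm(8000 * 30) * 0.05
  a1 <- audio_recording(x, 8000)
  a2 <- audio_recording(2 * x, 8000)
  s1 <- acoustic_stats(a1); s2 <- acoustic_stats(a2)
  expect_equal(s2$spl_mean - s1$spl_mean, 20 * log10(2), tolerance = 1e-6)
  expect_equal(s2$energy_total / s1$energy_total, 4, tolerance = 1e-9)
  # scale-invariant features unchanged
  expect_equal(s1$instfreq_mean, s2$instfreq_mean, tolerance = 1e-9)
  expect_equal(s1$lf_power_ratio, s2$lf_power_ratio, tolerance = 1e-9)
  # band energies sum to the total
  bsum <- s1$energy_b1 + s1$energy_b2 + s1$energy_b3 + s1$energy_b4 + s1$energy_b5
  expect_lte(bsum, s1$energy_total * (1 + 1e-9))

  silence <- audio_recording(numeric(8000 * 5), 8000)
  s0 <- acoustic_stats(silence)
  expect_equal(s0$spl_mean, -120)
  expect_equal(s0$energy_total, 0)
})

test_that("snore bursts raise the low-frequency band share", {
  set.seed(37)
  hyp <- hypnogram(rep("N2", 2))
  cfg_snore <- synth_config(duration_s = 600, snore_prob = 1, snore_amp = 0.3)
  cfg_quiet <- synth_config(duration_s = 600, snore_prob = 0)
  a_snore <- synth_audio(hyp, cfg_snore)
  set.seed(37)
  a_quiet <- synth_audio(hyp, cfg_quiet)
  r_snore <- acoustic_stats(a_snore)$lf_power_ratio
  r_quiet <- acoustic_stats(a_quiet)$lf_power_ratio
  expect_gt(r_snore, r_quiet)
})

test_that("the spectral gate attenuates a stationary hum but keeps a tone", {
  sr <- 8000
  t <- seq(0, 10, by = 1 / sr)
  hum <- 0.1 * sin(2 * pi * 60 * t)
  tone_sig <- 0.3 * sin(2 * pi * 800 * t)
  mixed <- audio_recording(hum + tone_sig, sr)
  profile <- audio_recording(hum[seq_len(2 * sr)], sr)
  gated <- noise_gate(mixed, profile)
  expect_equal(length(gated$samples), length(mixed$samples))
  band_energy <- function(a, lo, hi) {
    spec <- audio_spectrogram(a)
    sel <- spec$freq >= lo & spec$freq < hi
    sum(spec$power[, sel])
  }
  hum_att <- 10 * log10(band_energy(mixed, 40, 80) / band_energy(gated, 40, 80))
  tone_att <- 10 * log10(band_energy(mixed, 780, 820) / band_energy(gated, 780, 820))
  expect_gt(hum_att, 10)
  expect_lt(tone_att, 1)

  # zero-noise profile leaves the signal essentially unchanged
  silent_profile <- audio_recording(numeric(2 * sr), sr)
  passed <- noise_gate(mixed, silent_profile)
  expect_equal(passed$samples, mixed$samples, tolerance = 1e-6)

  # profile equal to a stationary input removes nearly everything
  hum_only <- audio_recording(hum, sr)
  gated_all <- noise_gate(hum_only, audio_recording(hum[seq_len(4 * sr)], sr))
  expect_lt(sqrt(mean(gated_all$samples^2)) / sqrt(mean(hum^2)), 0.1)
})
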