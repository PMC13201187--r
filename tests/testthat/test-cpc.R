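make_seg <- function(seed = 1, f = NULL, amp = 1, noise = 1) {
  set.seed(seed)
  t <- seq(0, by = 0.5, length.out = 1024)
  x <- noise * rnorm(1024)
  if (!is.null(f)) x <- x + amp * sin(2 * pi * f * t)
  x
}

test_that("self-coherence is 1 at powered frequencies", {
  x <- make_seg(21, f = 0.3, amp = 3)
  spec <- cpc_window(x, x)
  powered <- spec$cross_power > max(spec$cross_power) * 1e-6
  expect_true(all(abs(spec$coherence[powered] - 1) < 1e-6))
})

test_that("coherence is bounded in [0, 1] for arbitrary inputs", {
  set.seed(22)
  for (rep in 1:25) {
    spec <- cpc_window(rnorm(1024), rnorm(1024))
    expect_true(all(spec$coherence >= 0 & spec$coherence <= 1))
    expect_true(all(spec$cpc >= 0))
    expect_true(all(spec$cpc[spec$cross_power == 0] == 0))
  }
})

test_that("independent noise gives the small-sample coherence bias, not 1", {
  set.seed(23)
  mc <- replicate(40, mean(cpc_window(rnorm(1024), rnorm(1024))$coherence))
  # three 50%-overlapping averaged segments: expectation well below 1,
  # well above 0 (Monte-Carlo characterization)
  expect_gt(mean(mc), 0.15)
  expect_lt(mean(mc), 0.65)
})

test_that("a shared sinusoid produces a coherence peak at its frequency", {
  x <- make_seg(24, f = 0.3, amp = 2)
  set.seed(25)
  shared <- sin(2 * pi * 0.3 * seq(0, by = 0.5, length.out = 1024))
  y <- 2 * shared + rnorm(1024)
  spec <- cpc_window(x, y)
  at_peak <- which.min(abs(spec$freq - 0.3))
  background <- spec$coherence[spec$freq < 0.2 | spec$freq > 0.4]
  expect_gt(spec$coherence[at_peak], mean(background) + 2 * sd(background))
})

test_that("swapping inputs and scaling behave as the magnitudes dictate", {
  x <- make_seg(26, f = 0.25, amp = 1.5)
  y <- make_seg(27, f = 0.25, amp = 1.5)
  a <- cpc_window(x, y)
  b <- cpc_window(y, x)
  expect_equal(a$cross_power, b$cross_power, tolerance = 1e-12)
  expect_equal(a$coherence, b$coherence, tolerance = 1e-12)
  # scaling one signal by lambda scales |P_xy|^2 by lambda^2
  c2 <- cpc_window(3 * x, y)
  expect_equal(c2$cross_power, 9 * a$cross_power, tolerance = 1e-9)
  expect_equal(c2$coherence, a$coherence, tolerance = 1e-9)
})

test_that("constant segments are flagged with zero coherence", {
  spec <- cpc_window(rep(1, 1024), rep(2, 1024))
  expect_true(all(spec$coherence == 0))
  expect_error(cpc_window(rnorm(100), rnorm(100)),
               class = "bcgsleep_parameter_error")
})

test_that("per-epoch coupling features track a coupling switch-on", {
  # session in which the respiration modulation of the beat intervals is
  # absent in the first half and strong in the second half
  dur <- 1800
  tv <- 0:(dur - 1)
  f_resp <- 14 / 60
  set.seed(28)
  gain <- ifelse(tv < dur / 2, 0, 1)
  bdr <- 14 + 1.5 * sin(2 * pi * f_resp * tv) + rnorm(dur, 0, 0.2)
  vit <- vitals_series(tv, rep(60, dur), pmax(bdr, 0), rep(50, dur))
  t <- 0; tt <- c(); jj <- c()
  while (t < dur) {
    g <- if (t < dur / 2) 0 else 40
    val <- 1000 + g * sin(2 * pi * f_resp * t) + rnorm(1, 0, 5)
    tt <- c(tt, t + val / 1000); jj <- c(jj, val); t <- t + val / 1000
  }
  ses <- sleep_session("s", "x", beat_series(tt, jj), vit)
  cpc <- cpc_series(ses)
  full <- cpc[!cpc$partial, ]
  first <- full$cpc_hf[full$epoch >= 17 & full$epoch <= 29]  # windows fully pre-switch
  second <- full$cpc_hf[full$epoch >= 48]                    # windows fully post-switch
  expect_gt(median(second), 5 * median(first))
})

test_that("1024 samples at 2 Hz span 512 s and stationary sessions are stable", {
  expect_equal(1024 / 2, 512)
  ses <- toy_session(duration_s = 900, seed = 31)
  cpc <- cpc_series(ses)
  expect_equal(nrow(cpc), ses$n_epochs)
  full <- cpc[!cpc$partial, ]
  expect_true(all(is.finite(full$cpc_total)))
})
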