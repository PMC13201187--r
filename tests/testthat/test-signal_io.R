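test_that("epoch grid is floor(duration/30) half-open windows", {
  v <- vitals_series(0:599, rep(60, 600), rep(14, 600), rep(50, 600))
  b <- beat_series(seq(0.5, 599.5, by = 1), rep(1000, 600))
  ses <- sleep_session("s", "x", b, v)
  g <- epoch_grid(ses)
  expect_equal(nrow(g), 20)
  expect_equal(g$start_s, seq(0, 570, by = 30))
  expect_equal(g$end_s, g$start_s + 30)

  # 89 s -> 2 epochs (floor)
  v2 <- vitals_series(0:88, rep(60, 89), rep(14, 89), rep(50, 89))
  b2 <- beat_series(seq(0.5, 88.5, 1), rep(1000, 89))
  expect_equal(sleep_session("s", "x", b2, v2)$n_epochs, 2)

  # shorter than one epoch refuses
  v3 <- vitals_series(0:19, rep(60, 20), rep(14, 20), rep(50, 20))
  b3 <- beat_series(seq(0.5, 19.5, 1), rep(1000, 20))
  expect_error(sleep_session("s", "x", b3, v3), class = "bcgsleep_empty_grid_error")
})

test_that("a ~3 h session yields about 400 epochs", {
  n <- 10800
  v <- vitals_series(0:(n - 1), rep(60, n), rep(14, n), rep(50, n))
  b <- beat_series(seq(0.5, n - 0.5, 1), rep(1000, n))
  expect_equal(sleep_session("s", "x", b, v)$n_epochs, 360)
})

test_that("hypnogram and vitals round-trip through CSV", {
  h <- hypnogram(c("W", "N1", "N2"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_hypnogram(h, path)
  expect_equal(read_hypnogram(path), h, ignore_attr = TRUE)
  expect_equal(read_hypnogram(path)$stage, c("W", "N1", "N2"))

  # empty hypnogram: header-only file reads back empty
  h0 <- hypnogram(character(0))
  write_hypnogram(h0, path)
  expect_equal(nrow(read_hypnogram(path)), 0)

  v <- vitals_series(0:9, 60 + (0:9) / 10, rep(14.25, 10), rep(50.5, 10))
  vp <- withr::local_tempfile(fileext = ".csv")
  write_vitals(v, vp)
  v2 <- read_vitals(vp)
  expect_equal(v2$hr, v$hr)
  expect_equal(v2$sv, v$sv)
})

test_that("stage outside the alphabet is refused", {
  expect_error(hypnogram(c("W", "XX")), class = "bcgsleep_invariant_error")
})

test_that("beat files with invalid rows raise parse errors naming the row", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(t = c(0, 1, 2), jj_ms = c(800, -5, 820)), path)
  expect_error(read_beats(path), "row 2", class = "bcgsleep_parse_error")
})

test_that("offsets shift streams onto the session clock and invert exactly", {
  skip_if_not_installed("withr")
  dir <- withr::local_tempdir()
  n <- 120
  readr::write_csv(tibble::tibble(t = 0:(n - 1), hr = rep(60, n),
                                  bdr = rep(14, n), sv = rep(50, n)),
                   file.path(dir, "vitals.csv"))
  readr::write_csv(tibble::tibble(t = seq(3.5, n + 2.5, 1), jj_ms = rep(1000, n)),
                   file.path(dir, "beats.csv"))
  manifest <- list(subject_id = "s1", session_id = "a",
                   files = list(beats = "beats.csv", vitals = "vitals.csv"),
                   offsets = list(beats = 3.0, vitals = 0))
  ses <- read_session(manifest, base_dir = dir)
  # beat recorded at t appears at session time t - 3
  expect_equal(ses$beats$t[1], 0.5)
  # round trip: applying +offset then -offset restores timestamps
  t0 <- seq(3.5, 10.5, 1)
  expect_identical(t0 - 3 + 3, t0)
})

test_that("mono WAV round-trips at both encodings", {
  x <- sin(2 * pi * 440 * seq(0, 0.5, by = 1 / 8000)) * 0.5
  a <- audio_recording(x, 8000)
  p16 <- withr::local_tempfile(fileext = ".wav")
  write_wav(a, p16, bits = 16)
  r16 <- read_wav(p16)
  expect_equal(r16$sample_rate, 8000)
  expect_equal(r16$samples, x, tolerance = 1e-4)
  p32 <- withr::local_tempfile(fileext = ".wav")
  write_wav(a, p32, bits = 32)
  expect_equal(read_wav(p32)$samples, x, tolerance = 1e-7)
})
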