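test_that("Markov hypnogram matches its stationary distribution", {
  cfg <- synth_config(duration_s = 600)
  set.seed(61)
  h <- sample_hypnogram(cfg, n_epochs = 1e5)
  emp <- table(factor(h$stage, levels = c("W", "N1", "N2", "N3", "REM"))) / 1e5
  # stationary distribution by eigen-analysis of the transition matrix
  ev <- eigen(t(cfg$transition))
  stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  stat <- stat / sum(stat)
  expect_true(all(abs(as.numeric(emp) - stat) < 0.02))
  # N2 is the most frequent sleep stage under the defaults
  expect_equal(names(which.max(emp[c("N1", "N2", "N3", "REM")])), "N2")
})

test_that("identity transitions are absorbing and seeds reproduce", {
  cfg <- synth_config(duration_s = 600, transition = diag(5))
  set.seed(62)
  h <- sample_hypnogram(cfg, n_epochs = 50)
  expect_true(all(h$stage == "W"))

  s1 <- synth_session(synth_config(duration_s = 660), seed = 77)
  s2 <- synth_session(synth_config(duration_s = 660), seed = 77)
  expect_identical(s1$beats, s2$beats)
  expect_identical(s1$vitals, s2$vitals)
  expect_identical(s1$audio$samples, s2$audio$samples)
  expect_identical(s1$hypnogram, s2$hypnogram)
})

test_that("generated beat intervals track the configured stage heart rate", {
  cfg <- synth_config(duration_s = 600,
                      transition = {
                        m <- matrix(0, 5, 5,
                                    dimnames = list(c("W","N1","N2","N3","REM"),
                                                    c("W","N1","N2","N3","REM")))
                        diag(m) <- 1
                        m
                      })
  set.seed(63)
  hyp <- hypnogram(rep("N3", 20))
  card <- bcgsleep:::synth_cardiac(hyp, cfg)
  expect_equal(mean(card$beats$jj_ms), 60000 / cfg$hr_bpm[["N3"]],
               tolerance = 0.01)
})

test_that("zero coupling removes coherence at the respiratory frequency", {
  mk <- function(gain) {
    cfg <- synth_config(duration_s = 900,
                        coupling = c(W = gain, N1 = gain, N2 = gain,
                                     N3 = gain, REM = gain),
                        dropout_rate = 0)
    set.seed(64)
    hyp <- hypnogram(rep("N2", 30))
    card <- bcgsleep:::synth_cardiac(hyp, cfg)
    ses <- sleep_session("s", "x", card$beats, card$vitals)
    cpc <- cpc_series(ses)
    median(cpc$cpc_hf[!cpc$partial])
  }
  expect_gt(mk(2), 20 * mk(0))
})

test_that("cohorts are deterministic with real between-subject variance", {
  cfg <- synth_config(duration_s = 600)
  c1 <- make_cohort(n_subjects = 3, sessions_each = 2, base_seed = 5,
                    cfg = cfg, audio = FALSE)
  c2 <- make_cohort(n_subjects = 3, sessions_each = 2, base_seed = 5,
                    cfg = cfg, audio = FALSE)
  expect_equal(nrow(c1), 6)
  expect_identical(c1$session_obj[[4]]$beats, c2$session_obj[[4]]$beats)
  # subject effects: between-subject variance in mean heart rate
  hr_mean <- sapply(c1$session_obj, function(s) mean(s$vitals$hr))
  subj <- c1$subject
  fit <- stats::aov(hr_mean ~ subj)
  expect_gt(summary(fit)[[1]][["F value"]][1], 1)
})

test_that("streamed cohort features equal the two-step path", {
  cfg <- synth_config(duration_s = 630)
  two_step <- cohort_features(make_cohort(n_subjects = 2, sessions_each = 1,
                                          base_seed = 8, cfg = cfg))
  streamed <- synth_cohort_features(n_subjects = 2, sessions_each = 1,
                                    base_seed = 8, cfg = cfg)
  expect_identical(streamed$subject, two_step$subject)
  expect_equal(as.data.frame(streamed$features[[1]]),
               as.data.frame(two_step$features[[1]]))
  expect_identical(streamed$labels, two_step$labels)
})

test_that("nine subjects with three sessions give 27 sleep cycles", {
  cfg <- synth_config(duration_s = 600)
  co <- make_cohort(n_subjects = 9, sessions_each = 3, base_seed = 1,
                    cfg = cfg, audio = FALSE)
  expect_equal(nrow(co), 27)
  expect_equal(length(unique(co$subject)), 9)
})
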