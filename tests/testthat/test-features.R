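ses_cache <- new.env()

cached_session <- function() {
  if (is.null(ses_cache$ses)) {
    ses_cache$ses <- synth_session(synth_config(duration_s = 630), seed = 71,
                                   audio = TRUE)
    ses_cache$fm <- assemble_features(ses_cache$ses)
  }
  list(ses = ses_cache$ses, fm = ses_cache$fm)
}

test_that("the assembled matrix has one row per epoch and 62 features", {
  x <- cached_session()
  expect_equal(nrow(x$fm), x$ses$n_epochs)
  expect_equal(length(feature_columns(x$fm)), 62)
  expect_setequal(feature_columns(x$fm), feature_dictionary()$name)
  expect_equal(nrow(feature_dictionary()), 62)
})

test_that("assembly is deterministic", {
  x <- cached_session()
  fm2 <- assemble_features(x$ses)
  expect_equal(as.data.frame(x$fm), as.data.frame(fm2))
})

test_that("sessions without audio get flagged-missing audio columns", {
  ses <- synth_session(synth_config(duration_s = 630), seed = 72, audio = FALSE)
  expect_warning(fm <- assemble_features(ses), "audio")
  aud_cols <- grep("^aud_", feature_columns(fm), value = TRUE)
  expect_equal(length(aud_cols), 19)
  expect_true(all(is.na(as.matrix(fm[, aud_cols]))))
  bcg_cols <- setdiff(feature_columns(fm), aud_cols)
  expect_equal(length(bcg_cols), 43)
  full <- fm[!fm$partial, ]
  expect_gt(mean(is.finite(as.matrix(full[, bcg_cols]))), 0.95)
})

test_that("normalization uses training statistics only", {
  x <- cached_session()
  fm <- x$fm
  half <- nrow(fm) %/% 2
  train <- fm[seq_len(half), ]
  class(train) <- class(fm)
  test <- fm[(half + 1):nrow(fm), ]
  class(test) <- class(fm)
  # the short training half leaves some coupling columns constant (every
  # left-truncated window reuses the first full coupling window)
  norm <- suppressWarnings(normalize_features(list(train), apply_to = list(train, test)))
  cols <- feature_columns(fm)
  tr_n <- norm$matrices[[1]]
  means <- sapply(cols, function(cl) mean(tr_n[[cl]], na.rm = TRUE))
  sds <- sapply(cols, function(cl) sd(tr_n[[cl]], na.rm = TRUE))
  varying <- sapply(cols, function(cl) {
    s <- sd(train[[cl]], na.rm = TRUE); is.finite(s) && s > 0
  })
  expect_true(all(abs(means[varying]) < 1e-9))
  expect_true(all(abs(sds[varying] - 1) < 1e-9))
  # held-out data transformed with training constants, not its own
  te_n <- norm$matrices[[2]]
  cl <- "mean_jj"
  expect_equal(te_n[[cl]],
               (test[[cl]] - norm$center[[cl]]) / norm$scale[[cl]])

  # all-constant column untouched with warning
  train2 <- train
  train2$mean_jj <- 5
  class(train2) <- class(fm)
  expect_warning(n2 <- normalize_features(list(train2)), "zero-variance")
  expect_equal(n2$matrices[[1]]$mean_jj, rep(5 - 5, nrow(train2)))
})

test_that("imputation policies behave as documented", {
  x <- cached_session()
  fm <- x$fm
  fm$sdnn[5] <- NA
  fm$sdnn[1] <- NA
  cf <- impute_features(fm, "carry-forward")
  expect_equal(cf$sdnn[5], fm$sdnn[4])
  expect_equal(cf$sdnn[1], median(fm$sdnn, na.rm = TRUE))  # leading gap
  cm <- impute_features(fm, "column-median")
  expect_equal(cm$sdnn[5], median(fm$sdnn, na.rm = TRUE))
  expect_identical(impute_features(fm, "none")$sdnn, fm$sdnn)
  expect_false(anyNA(as.matrix(cf[, feature_columns(cf)])[!fm$partial, "sdnn"]))
})

test_that("HRV features obey shift and scale equivariance", {
  set.seed(73)
  jj <- rnorm(150, 900, 40)
  c_shift <- 200
  lambda <- 1.7
  td <- hrv_time_domain(jj); td_s <- hrv_time_domain(jj + c_shift)
  expect_equal(td_s$mean_jj, td$mean_jj + c_shift)
  expect_equal(td_s$sdnn, td$sdnn)
  expect_equal(td_s$rmssd, td$rmssd)
  td_l <- hrv_time_domain(lambda * jj)
  expect_equal(td_l$sdnn, lambda * td$sdnn)
  expect_equal(td_l$rmssd, lambda * td$rmssd)

  ps <- poincare_sd(jj)
  expect_equal(poincare_sd(jj + c_shift)$sd1, ps$sd1)
  expect_equal(poincare_sd(jj + c_shift)$sd2, ps$sd2)
  expect_equal(poincare_sd(lambda * jj)$sd1, lambda * ps$sd1)
  expect_equal(poincare_sd(lambda * jj)$sd2, lambda * ps$sd2)

  st <- sta_features(jj); st_s <- sta_features(jj + c_shift)
  expect_equal(st_s$sta_d_q1, st$sta_d_q1)
  expect_equal(st_s$sta_d_q2, st$sta_d_q2)

  se <- sample_approx_entropy(jj)
  expect_equal(sample_approx_entropy(jj + c_shift)$sampen, se$sampen)
  expect_equal(sample_approx_entropy(lambda * jj)$sampen, se$sampen)

  d <- dfa(jj)
  expect_equal(dfa(jj + c_shift)$dfa_alpha1, d$dfa_alpha1, tolerance = 1e-10)
})

test_that("fully masked windows yield flagged missing values, never zero", {
  expect_false(hrv_time_domain(numeric(0))$ok)
  expect_true(is.na(hrv_time_domain(numeric(0))$sdnn))
  expect_false(poincare_sd(numeric(0))$ok)
  expect_false(sta_features(numeric(0))$ok)
  expect_false(sample_approx_entropy(numeric(0))$ok)
  expect_false(renyi_entropy(numeric(0))$ok[1])
  expect_false(device_hrv(numeric(0), 1, 1)$ok)
})
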