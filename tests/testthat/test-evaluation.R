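test_that("LOSO folds partition the subjects", {
  f <- loso_folds(paste0("S", 1:9))
  expect_equal(nrow(f), 9)
  expect_setequal(f$held_out, paste0("S", 1:9))
  for (i in seq_len(nrow(f))) {
    expect_length(intersect(f$held_out[i], f$training[[i]]), 0)
    expect_setequal(c(f$held_out[i], f$training[[i]]), paste0("S", 1:9))
  }
  f2 <- loso_folds(c("a", "b"))
  expect_equal(nrow(f2), 2)
  expect_error(loso_folds(c("a", "a")), class = "bcgsleep_parameter_error")
  expect_error(loso_folds("a"), class = "bcgsleep_parameter_error")
})

test_that("3-class relabeling merges non-REM and is idempotent", {
  expect_equal(relabel_3class(c("W", "N1", "N2", "N3", "REM")),
               c("W", "NREM", "NREM", "NREM", "REM"))
  expect_equal(relabel_3class(rep("W", 5)), rep("W", 5))
  x <- c("W", "NREM", "REM")
  expect_equal(relabel_3class(x), x)
  expect_error(relabel_3class("N4"), class = "bcgsleep_parameter_error")
  h <- hypnogram(c("W", "N2", "REM"))
  h3 <- relabel_3class(h)
  expect_s3_class(h3, "hypnogram")
  expect_equal(h3$stage, c("W", "NREM", "REM"))
})

test_that("confusion metrics match hand arithmetic on a toy table", {
  cm <- matrix(c(5, 1, 0,
                 2, 6, 0,
                 0, 1, 5), 3, 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  m <- confusion_metrics(cm)
  expect_equal(m$accuracy, 16 / 20)
  expect_equal(m$per_stage$sensitivity[1], 5 / 6)
  expect_equal(m$per_stage$precision[1], 5 / 7)
  expect_equal(m$per_stage$specificity[1], 12 / 14)
  # row sums equal reference counts by construction
  expect_equal(unname(rowSums(cm)), c(6, 8, 6))

  # perfect agreement
  ref <- c("a", "b", "c", "a")
  m2 <- confusion_metrics(confusion_matrix(ref, ref, c("a", "b", "c")))
  expect_equal(m2$accuracy, 1)
  expect_true(all(m2$per_stage$f1 == 1))

  # single-class ref and matching pred: other stages undefined
  m3 <- confusion_metrics(confusion_matrix(rep("a", 4), rep("a", 4),
                                           c("a", "b")))
  expect_equal(m3$accuracy, 1)
  expect_true(is.na(m3$per_stage$sensitivity[2]))
})

test_that("Cohen's kappa matches hand arithmetic and the null", {
  ref <- c(rep("x", 25), rep("y", 25))
  pred <- c(rep("x", 20), rep("y", 5), rep("x", 10), rep("y", 15))
  expect_equal(cohens_kappa(ref, pred), 0.4)  # p_o 0.7, p_e 0.5

  expect_equal(cohens_kappa(c("a", "b", "a"), c("a", "b", "a")), 1)

  # independent predictions with matched marginals: kappa near 0
  set.seed(51)
  ref_big <- sample(c("W", "NREM", "REM"), 20000, TRUE, prob = c(0.2, 0.65, 0.15))
  pred_big <- sample(c("W", "NREM", "REM"), 20000, TRUE, prob = c(0.2, 0.65, 0.15))
  expect_lt(abs(cohens_kappa(ref_big, pred_big)), 0.03)
})

test_that("kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(52)
  for (rep in 1:5) {
    ref <- sample(c("W", "N1", "N2"), 200, TRUE)
    pred <- sample(c("W", "N1", "N2"), 200, TRUE)
    tab <- table(ref, pred)
    expect_equal(cohens_kappa(ref, pred),
                 e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
  }
})

test_that("fold aggregation computes mean, sample SD and pooled counts", {
  mk <- function(acc) {
    cm <- matrix(c(acc * 10, 10 - acc * 10, 0, 10), 2, 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("a", "b")))
    list(cm = cm, accuracy = acc, kappa = acc - 0.1,
         per_stage = confusion_metrics(cm)$per_stage)
  }
  agg <- aggregate_folds(list(mk(0.6), mk(0.8)))
  expect_equal(agg$summary$mean[agg$summary$metric == "accuracy"], 0.7)
  expect_equal(agg$summary$sd[agg$summary$metric == "accuracy"],
               sd(c(0.6, 0.8)))
  expect_equal(agg$summary$sd[agg$summary$metric == "accuracy"], 0.1414,
               tolerance = 1e-3)
  expect_equal(sum(agg$pooled_cm), 40)

  agg2 <- aggregate_folds(list(mk(0.7), mk(0.7), mk(0.7)))
  expect_equal(agg2$summary$sd, c(0, 0))
})

test_that("pooled-matrix metrics equal metrics on concatenated sequences", {
  set.seed(53)
  classes <- c("W", "NREM", "REM")
  refs <- lapply(1:3, function(i) sample(classes, 50, TRUE))
  preds <- lapply(1:3, function(i) sample(classes, 50, TRUE))
  folds <- lapply(1:3, function(i) {
    cm <- confusion_matrix(refs[[i]], preds[[i]], classes)
    c(list(cm = cm), confusion_metrics(cm)[c("accuracy", "kappa")],
      list(per_stage = confusion_metrics(cm)$per_stage))
  })
  agg <- aggregate_folds(folds)
  all_cm <- confusion_matrix(unlist(refs), unlist(preds), classes)
  expect_identical(agg$pooled_cm, all_cm)
  expect_equal(agg$pooled_accuracy, confusion_metrics(all_cm)$accuracy)
})
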