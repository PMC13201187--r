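# Leave-one-subject-out evaluation: fold planning, 3-class relabeling,
# confusion matrices, accuracy, Cohen's kappa and one-vs-rest per-stage
# metrics with cross-fold mean and SD.

#' Leave-one-subject-out fold plan
#'
#' One fold per subject; all sessions of the held-out subject travel
#' together, and the training and held-out subject sets of every fold
#' are disjoint by construction.
#'
#' @param subjects Character/integer vector of unique subject ids.
#' @return Tibble `fold, held_out, training` (training is a list column).
#' @export
loso_folds <- function(subjects) {
  subjects <- as.character(subjects)
  if (anyDuplicated(subjects)) {
    abort("duplicate subject ids", class = "bcgsleep_parameter_error")
  }
  if (length(subjects) < 2) {
    abort("need at least 2 subjects for LOSO", class = "bcgsleep_parameter_error")
  }
  tibble(fold = seq_along(subjects), held_out = subjects,
         training = map(subjects, ~ setdiff(subjects, .x)))
}

#' Relabel a 5-class hypnogram to 3 classes
#'
#' `W -> W`, `{N1, N2, N3} -> NREM`, `REM -> REM`; length preserved and
#' idempotent on already-3-class input.
#'
#' @param stages Character vector of stage labels (or a [hypnogram()]).
#' @return Same type as the input, relabeled.
#' @export
relabel_3class <- function(stages) {
  if (inherits(stages, "hypnogram")) {
    out <- hypnogram(relabel_3class(stages$stage), alphabet = STAGES_3)
    return(out)
  }
  known <- c(STAGES_5, "NREM")
  bad <- setdiff(unique(stages), known)
  if (length(bad)) {
    abort(sprintf("unknown stage label '%s'", bad[1]),
          class = "bcgsleep_parameter_error")
  }
  ifelse(stages %in% c("N1", "N2", "N3"), "NREM", stages)
}

#' Confusion matrix of two label sequences
#'
#' Rows are reference stages, columns predictions; row sums equal the
#' reference stage counts.
#'
#' @param ref,pred Equal-length label vectors.
#' @param classes Class order.
#' @return Integer matrix `classes x classes`.
#' @export
confusion_matrix <- function(ref, pred, classes) {
  if (length(ref) != length(pred)) {
    abort("ref and pred must have equal length", class = "bcgsleep_parameter_error")
  }
  table(factor(ref, levels = classes), factor(pred, levels = classes)) |>
    unclass()
}

#' Accuracy, kappa and per-stage metrics from a confusion matrix
#'
#' One-vs-rest per stage: sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)` and F1; overall accuracy is
#' `trace/total` and kappa is computed from the marginals. Stages absent
#' from both reference and prediction get NA metrics (excluded from fold
#' averaging, never zero-filled).
#'
#' @param cm Confusion matrix (reference rows, prediction columns).
#' @return List with `accuracy`, `kappa`, and `per_stage` tibble
#'   (`stage, sensitivity, specificity, precision, f1, n_ref`).
#' @export
confusion_metrics <- function(cm) {
  total <- sum(cm)
  acc <- sum(diag(cm)) / total
  per <- map(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    if (tp + fn + fp == 0) {
      return(tibble(stage = rownames(cm)[i], sensitivity = NA_real_,
                    specificity = NA_real_, precision = NA_real_,
                    f1 = NA_real_, n_ref = 0L))
    }
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    f1 <- if (is.finite(prec) && is.finite(sens) && prec + sens > 0) {
      2 * prec * sens / (prec + sens)
    } else NA_real_
    tibble(stage = rownames(cm)[i], sensitivity = sens, specificity = spec,
           precision = prec, f1 = f1, n_ref = as.integer(tp + fn))
  })
  list(accuracy = acc, kappa = kappa_from_cm(cm), per_stage = bind_rows(per))
}

kappa_from_cm <- function(cm) {
  total <- sum(cm)
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (pe >= 1) return(1)  # both raters constant and equal, by convention
  (po - pe) / (1 - pe)
}

#' Cohen's kappa of two label sequences
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with chance agreement `p_e` from the
#' marginal products. When both sequences are the same constant
#' (`p_e = 1`), kappa is defined as 1 by convention.
#'
#' @param ref,pred Equal-length label vectors.
#' @param classes Class set (default: union of observed labels).
#' @return Numeric kappa.
#' @export
cohens_kappa <- function(ref, pred, classes = sort(union(unique(ref), unique(pred)))) {
  if (length(ref) != length(pred) || length(ref) < 1) {
    abort("ref and pred must have equal positive length",
          class = "bcgsleep_parameter_error")
  }
  kappa_from_cm(confusion_matrix(ref, pred, classes))
}

fold_report <- function(ref, pred, classes) {
  cm <- confusion_matrix(ref, pred, classes)
  m <- confusion_metrics(cm)
  list(cm = cm, accuracy = m$accuracy, kappa = m$kappa, per_stage = m$per_stage)
}

#' Aggregate per-fold metric reports
#'
#' Cross-fold mean and sample SD for accuracy, kappa and each per-stage
#' metric (undefined per-stage values are excluded from averaging), plus
#' the pooled confusion matrix. Pooled-over-epochs accuracy/kappa are
#' also reported.
#'
#' @param folds List of fold reports as produced internally by
#'   [loso_train_eval()] (each with `cm`, `accuracy`, `kappa`,
#'   `per_stage`).
#' @return List with `summary` (tibble `metric, mean, sd`), `per_stage`
#'   (tibble `stage, metric, mean, sd, n_folds`), `pooled_cm`,
#'   `pooled_accuracy`, `pooled_kappa`, `per_fold`.
#' @export
aggregate_folds <- function(folds) {
  stopifnot(length(folds) >= 1)
  acc <- map_dbl(folds, "accuracy")
  kap <- map_dbl(folds, "kappa")
  summary <- tibble(metric = c("accuracy", "kappa"),
                    mean = c(mean(acc), mean(kap)),
                    sd = c(if (length(acc) > 1) sd(acc) else 0,
                           if (length(kap) > 1) sd(kap) else 0))
  per <- bind_rows(imap(folds, ~ mutate(.x$per_stage, fold = .y))) |>
    tidyr::pivot_longer(cols = c("sensitivity", "specificity", "precision", "f1"),
                        names_to = "metric", values_to = "value") |>
    filter(is.finite(.data$value)) |>
    group_by(.data$stage, .data$metric) |>
    summarise(mean = mean(.data$value),
              sd = if (dplyr::n() > 1) sd(.data$value) else 0,
              n_folds = dplyr::n(), .groups = "drop")
  pooled <- Reduce(`+`, map(folds, "cm"))
  pm <- confusion_metrics(pooled)
  per_fold <- tibble(fold = seq_along(folds), accuracy = acc, kappa = kap)
  list(summary = summary, per_stage = per, pooled_cm = pooled,
       pooled_accuracy = pm$accuracy, pooled_kappa = pm$kappa,
       per_fold = per_fold)
}

#' Leave-one-subject-out training and evaluation
#'
#' Full LOSO loop over a cohort of sessions: per fold, feature matrices
#' of the training subjects are z-scored with training statistics only,
#' residual NAs are set to the (training) mean, the staging model is
#' trained on the training sequences and evaluated on the held-out
#' subject's sessions. Reports 5-class and relabeled 3-class metrics.
#'
#' @param cohort Tibble with columns `subject`, `session`, `features`
#'   (list of `feature_matrix`) and `labels` (list of per-epoch stage
#'   vectors).
#' @param config A [staging_config()] (its `input_dim` is overridden by
#'   the feature dictionary width).
#' @param hyper A [staging_hyper()].
#' @param seed Integer seed; fold f trains with seed `seed + f`.
#' @param permute_labels If TRUE, training labels are permuted within
#'   each session (a chance-level control); evaluation labels are
#'   untouched.
#' @param verbose Print progress.
#' @return A list of class `loso_report`: `report_5class`,
#'   `report_3class` (each from [aggregate_folds()]), `predictions`
#'   (tibble `subject, session, epoch, ref, pred`), `folds`, `config`,
#'   `seed`.
#' @export
loso_train_eval <- function(cohort, config = staging_config(),
                            hyper = staging_hyper(), seed = 1L,
                            permute_labels = FALSE, verbose = FALSE) {
  stopifnot(all(c("subject", "session", "features", "labels") %in% names(cohort)))
  n_feat <- length(feature_columns(cohort$features[[1]]))
  config$input_dim <- as.integer(n_feat)
  folds <- loso_folds(unique(cohort$subject))
  fold_5 <- list(); fold_3 <- list(); preds <- list()
  for (f in seq_len(nrow(folds))) {
    held <- folds$held_out[f]
    tr <- cohort[cohort$subject != held, ]
    te <- cohort[cohort$subject == held, ]
    stopifnot(length(intersect(tr$subject, te$subject)) == 0)  # fold audit
    norm <- normalize_features(tr$features, apply_to = c(tr$features, te$features))
    mats <- map(norm$matrices, function(m) {
      x <- as_model_input(m)
      x[!is.finite(x)] <- 0  # training-mean imputation after z-scoring
      x
    })
    x_tr <- mats[seq_len(nrow(tr))]
    x_te <- mats[nrow(tr) + seq_len(nrow(te))]
    y_tr <- tr$labels
    if (permute_labels) {
      y_tr <- map(y_tr, sample)
    }
    if (verbose) message(sprintf("fold %d/%d (held out: %s)", f, nrow(folds), held))
    fit <- train_staging_model(x_tr, y_tr, config = config, hyper = hyper,
                               seed = seed + f)
    pred <- map(x_te, function(x) predict(fit, x)$.pred_class)
    ref <- unlist(te$labels)
    prd <- unlist(pred)
    fold_5[[f]] <- fold_report(ref, prd, config$classes)
    fold_3[[f]] <- fold_report(relabel_3class(ref), relabel_3class(prd), STAGES_3)
    preds[[f]] <- tibble(subject = rep(te$subject, map_dbl(te$labels, length)),
                         session = rep(te$session, map_dbl(te$labels, length)),
                         epoch = unlist(map(te$labels, ~ seq_along(.x) - 1L)),
                         ref = ref, pred = prd)
  }
  structure(list(report_5class = aggregate_folds(fold_5),
                 report_3class = aggregate_folds(fold_3),
                 predictions = bind_rows(preds),
                 folds = folds, config = config, seed = seed,
                 permuted = permute_labels),
            class = "loso_report")
}

#' @export
print.loso_report <- function(x, ...) {
  s5 <- x$report_5class$summary
  s3 <- x$report_3class$summary
  cat(sprintf("<loso_report: %d folds%s>\n", nrow(x$folds),
              if (isTRUE(x$permuted)) ", permuted-label control" else ""))
  cat(sprintf("  5-class: accuracy %.1f%% +/- %.1f, kappa %.2f +/- %.2f\n",
              100 * s5$mean[1], 100 * s5$sd[1], s5$mean[2], s5$sd[2]))
  cat(sprintf("  3-class: accuracy %.1f%% +/- %.1f, kappa %.2f +/- %.2f\n",
              100 * s3$mean[1], 100 * s3$sd[1], s3$mean[2], s3$sd[2]))
  invisible(x)
}
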