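# broom-style tidiers for fitted objects and reports.

#' Tidy a staging fit's training log
#'
#' @param x A `staging_fit`.
#' @param ... Unused.
#' @return Tibble `pass, train_loss, val_loss`.
#' @export
tidy.staging_fit <- function(x, ...) x$log

#' One-row summary of a staging fit
#'
#' @param x A `staging_fit`.
#' @param ... Unused.
#' @return Tibble with variant, parameter count, passes, final and best
#'   training loss.
#' @export
glance.staging_fit <- function(x, ...) {
  tibble(variant = x$config$variant,
         n_parameters = count_parameters(x),
         n_passes = nrow(x$log),
         final_train_loss = x$log$train_loss[nrow(x$log)],
         best_loss = min(x$log$train_loss),
         seed = x$seed)
}

#' Tidy a LOSO report into long metric form
#'
#' One row per (scheme, fold, class, metric): per-fold accuracy and
#' kappa (class NA) plus per-stage sensitivity/specificity/precision/F1.
#'
#' @param x A `loso_report`.
#' @param ... Unused.
#' @return Tibble `scheme, fold, class, metric, value`.
#' @export
tidy.loso_report <- function(x, ...) {
  one <- function(rep, scheme) {
    overall <- rep$per_fold |>
      tidyr::pivot_longer(c("accuracy", "kappa"),
                          names_to = "metric", values_to = "value") |>
      mutate(scheme = scheme, class = NA_character_)
    per_stage <- rep$per_stage |>
      mutate(scheme = scheme, fold = NA_integer_) |>
      rename(class = "stage", value = "mean")
    bind_rows(select(overall, "scheme", "fold", "class", "metric", "value"),
              select(per_stage, "scheme", "fold", "class", "metric", "value"))
  }
  bind_rows(one(x$report_5class, "5class"), one(x$report_3class, "3class"))
}

#' One-row summary of a LOSO report
#'
#' @param x A `loso_report`.
#' @param ... Unused.
#' @return Tibble with fold count and fold-mean/SD accuracy and kappa for
#'   the 5-class and 3-class schemes (accuracy in percent), plus pooled
#'   values.
#' @export
glance.loso_report <- function(x, ...) {
  s5 <- x$report_5class$summary; s3 <- x$report_3class$summary
  tibble(n_folds = nrow(x$folds),
         accuracy_5class = 100 * s5$mean[s5$metric == "accuracy"],
         accuracy_5class_sd = 100 * s5$sd[s5$metric == "accuracy"],
         kappa_5class = s5$mean[s5$metric == "kappa"],
         kappa_5class_sd = s5$sd[s5$metric == "kappa"],
         accuracy_3class = 100 * s3$mean[s3$metric == "accuracy"],
         accuracy_3class_sd = 100 * s3$sd[s3$metric == "accuracy"],
         kappa_3class = s3$mean[s3$metric == "kappa"],
         kappa_3class_sd = s3$sd[s3$metric == "kappa"],
         pooled_accuracy_3class = 100 * x$report_3class$pooled_accuracy,
         pooled_kappa_3class = x$report_3class$pooled_kappa,
         seed = x$seed)
}
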