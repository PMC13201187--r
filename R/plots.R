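# ggplot2 visualisations for the main result types.

stage_levels_of <- function(stages) {
  if (all(unique(stages) %in% STAGES_3)) STAGES_3 else STAGES_5
}

#' Plot a hypnogram
#'
#' Classic staircase plot with deeper stages lower.
#'
#' @param object A [hypnogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hypnogram <- function(object, ...) {
  lev <- if (identical(attr(object, "alphabet"), STAGES_3)) {
    c("NREM", "REM", "W")
  } else c("N3", "N2", "N1", "REM", "W")
  df <- mutate(object, hours = .data$epoch * EPOCH_S / 3600,
               stage_f = factor(.data$stage, levels = lev))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hours, y = .data$stage_f,
                                   group = 1)) +
    ggplot2::geom_step(linewidth = 0.4) +
    ggplot2::labs(x = "time (h)", y = "stage") +
    ggplot2::theme_minimal()
}

#' Plot a cardiopulmonary coupling spectrum
#'
#' Cross power, coherence and their product against frequency.
#'
#' @param object A `cpc_spectrum` from [cpc_window()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cpc_spectrum <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            c("cross_power", "coherence", "cpc"),
                            names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frequency (Hz)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Poincare plot of a beat series
#'
#' Consecutive-interval scatter with the line of identity.
#'
#' @param beats A [beat_series()] (or numeric JJ vector, ms).
#' @return A ggplot.
#' @export
plot_poincare <- function(beats) {
  jj <- if (inherits(beats, "beat_series")) beats$jj_ms else as.numeric(beats)
  df <- tibble(jj_i = jj[-length(jj)], jj_i1 = jj[-1])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$jj_i, y = .data$jj_i1)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(JJ[i] ~ "(ms)"),
                  y = expression(JJ[i + 1] ~ "(ms)")) +
    ggplot2::theme_minimal()
}

#' Plot a LOSO report
#'
#' Per-fold accuracy and kappa for the 5-class and 3-class schemes.
#'
#' @param object A `loso_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.loso_report <- function(object, ...) {
  df <- tidy(object) |> filter(!is.na(.data$fold))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$value)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::facet_grid(metric ~ scheme, scales = "free_y") +
    ggplot2::labs(x = "fold (held-out subject)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a feature matrix
#'
#' Z-scored features by epoch; a quick visual check of stage-dependent
#' structure.
#'
#' @param matrix A `feature_matrix`.
#' @return A ggplot.
#' @export
plot_feature_matrix <- function(matrix) {
  cols <- feature_columns(matrix)
  df <- matrix[, c("epoch", cols)]
  for (cl in cols) {
    v <- df[[cl]]
    s <- sd(v, na.rm = TRUE)
    df[[cl]] <- if (is.finite(s) && s > 0) (v - mean(v, na.rm = TRUE)) / s else 0
  }
  long <- tidyr::pivot_longer(df, all_of(cols), names_to = "feature",
                              values_to = "z")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$feature,
                                     fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-3, 3), oob = scales_squish) +
    ggplot2::labs(x = "epoch", y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}

scales_squish <- function(x, range = c(-3, 3)) pmin(pmax(x, range[1]), range[2])
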