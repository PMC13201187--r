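# Training loop for the staging model: whole sessions as sequences
# (never shuffled or concatenated), class-weighted cross-entropy, Adam
# with gradient clipping, deterministic under one integer seed.

#' Training hyperparameters
#'
#' @param lr Adam learning rate (default 1e-3).
#' @param beta1,beta2,eps Adam moment constants.
#' @param max_passes Maximum passes over the training sequences
#'   (default 40).
#' @param patience Stop after this many passes without improvement of the
#'   monitored loss (validation loss when validation sequences are given,
#'   else training loss). Default 10.
#' @param clip Global gradient-norm clip (default 5).
#' @return A list of class `staging_hyper`.
#' @export
staging_hyper <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                          max_passes = 40L, patience = 10L, clip = 5) {
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 max_passes = as.integer(max_passes),
                 patience = as.integer(patience), clip = clip),
            class = "staging_hyper")
}

labels_to_index <- function(labels, classes) {
  idx <- match(labels, classes)
  if (any(is.na(idx) & !is.na(labels))) {
    abort(sprintf("label outside class set {%s}", paste(classes, collapse = ",")),
          class = "bcgsleep_parameter_error")
  }
  idx
}

#' Convert a feature matrix to model input
#'
#' Drops bookkeeping columns, orders columns by the feature dictionary
#' and returns a plain numeric matrix (epochs x features). NAs are kept;
#' impute (or normalize-then-zero-fill) before training.
#'
#' @param matrix A `feature_matrix` tibble.
#' @return Numeric matrix.
#' @export
as_model_input <- function(matrix) {
  cols <- feature_columns(matrix)
  as.matrix(matrix[, cols])
}

clip_global_norm <- function(grads, clip) {
  gn <- sqrt(tree_sum(grads, function(g) g^2))
  if (is.finite(gn) && gn > clip) {
    grads <- tree_map(function(g) g * (clip / gn), grads)
  }
  grads
}

#' Train the staging model
#'
#' Each training session is one sequence; sequences are visited in their
#' given order every pass (sleep cycles stay intact). The loss is
#' class-weighted cross-entropy per epoch with weights inverse to stage
#' frequency in the training set (absent classes get weight 0 with a
#' warning). One Adam update per sequence; gradients are clipped to a
#' global norm. A fixed seed reproduces the run (initialization and
#' dropout) exactly.
#'
#' @param x List of numeric matrices (epochs x features), one per
#'   training session, already normalized/imputed.
#' @param y List of per-epoch stage-label vectors aligned to `x`.
#' @param config A [staging_config()].
#' @param hyper A [staging_hyper()].
#' @param seed Integer seed.
#' @param validation Optional list `list(x = ..., y = ...)` of held-back
#'   sequences monitored for early stopping (never trained on).
#' @param verbose Print per-pass losses.
#' @return A `staging_fit`: trained parameters, config, class weights,
#'   training log (tibble `pass, train_loss, val_loss`), seed.
#' @export
train_staging_model <- function(x, y, config = staging_config(),
                                hyper = staging_hyper(), seed = 1L,
                                validation = NULL, verbose = FALSE) {
  stopifnot(is.list(x), is.list(y), length(x) == length(y), length(x) >= 1)
  for (i in seq_along(x)) {
    if (nrow(x[[i]]) != length(y[[i]])) {
      abort(sprintf("sequence %d: %d feature rows vs %d labels", i,
                    nrow(x[[i]]), length(y[[i]])),
            class = "bcgsleep_parameter_error")
    }
    if (anyNA(x[[i]])) {
      abort(sprintf("sequence %d contains NA features; impute first", i),
            class = "bcgsleep_parameter_error")
    }
  }
  classes <- config$classes
  yi <- map(y, labels_to_index, classes = classes)
  counts <- table(factor(unlist(y), levels = classes))
  present <- counts > 0
  if (!all(present)) {
    warn(sprintf("class(es) absent from training data: %s",
                 paste(classes[!present], collapse = ", ")))
  }
  w <- ifelse(present, sum(counts) / pmax(as.numeric(counts), 1), 0)
  w <- w / mean(w[present])  # renormalize over present classes

  model <- build_staging_model(config, seed = seed)
  m_state <- tree_map(function(p) p * 0, model$params)
  v_state <- tree_map(function(p) p * 0, model$params)
  step <- 0L
  log <- vector("list", hyper$max_passes)
  best <- Inf; best_params <- model$params; stale <- 0L

  for (pass in seq_len(hyper$max_passes)) {
    losses <- numeric(length(x))
    for (i in seq_along(x)) {
      fwd <- staging_forward(x[[i]], model, training = TRUE)
      ce <- weighted_ce(fwd$logits, yi[[i]], w)
      losses[i] <- ce$loss
      grads <- staging_backward(ce$dlogits, fwd, model)
      grads <- clip_global_norm(grads, hyper$clip)
      step <- step + 1L
      lr_t <- hyper$lr * sqrt(1 - hyper$beta2^step) / (1 - hyper$beta1^step)
      m_state <- tree_map(function(m, g) hyper$beta1 * m + (1 - hyper$beta1) * g,
                          m_state, grads)
      v_state <- tree_map(function(v, g) hyper$beta2 * v + (1 - hyper$beta2) * g^2,
                          v_state, grads)
      model$params <- tree_map(function(p, m, v) p - lr_t * m / (sqrt(v) + hyper$eps),
                               model$params, m_state, v_state)
    }
    val_loss <- NA_real_
    if (!is.null(validation)) {
      vl <- numeric(length(validation$x))
      vyi <- map(validation$y, labels_to_index, classes = classes)
      for (j in seq_along(validation$x)) {
        fwd <- staging_forward(validation$x[[j]], model, training = FALSE)
        vl[j] <- weighted_ce(fwd$logits, vyi[[j]], w)$loss
      }
      val_loss <- mean(vl)
    }
    monitored <- if (is.na(val_loss)) mean(losses) else val_loss
    log[[pass]] <- tibble(pass = pass, train_loss = mean(losses),
                          val_loss = val_loss)
    if (verbose) {
      message(sprintf("pass %d: train %.4f%s", pass, mean(losses),
                      if (is.na(val_loss)) "" else sprintf(" val %.4f", val_loss)))
    }
    if (monitored < best - 1e-6) {
      best <- monitored
      best_params <- model$params
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= hyper$patience) break
    }
  }
  structure(list(config = config, params = best_params,
                 class_weights = setNames(as.numeric(w), classes),
                 log = bind_rows(log[!map_lgl_null(log)]),
                 hyper = hyper, seed = seed,
                 feature_names = NULL),
            class = "staging_fit")
}

map_lgl_null <- function(x) vapply(x, is.null, logical(1))

#' Predict per-epoch stage probabilities
#'
#' Runs the trained model in evaluation mode (dropout inactive;
#' deterministic). Probabilities sum to one per epoch.
#'
#' @param object A `staging_fit`.
#' @param newdata Numeric matrix (epochs x features) matching the
#'   configured input dimension, without NAs.
#' @param ... Unused.
#' @return Tibble: `epoch`, one probability column per class
#'   (`.prob_<class>`), and `.pred_class`.
#' @export
predict.staging_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_matrix")) {
    if (!is.null(object$feature_names) &&
        !identical(object$feature_names, feature_columns(newdata))) {
      abort("feature columns do not match the model's feature dictionary",
            class = "bcgsleep_parameter_error")
    }
    newdata <- as_model_input(newdata)
  }
  if (ncol(newdata) != object$config$input_dim) {
    abort(sprintf("model expects %d features, got %d",
                  object$config$input_dim, ncol(newdata)),
          class = "bcgsleep_parameter_error")
  }
  if (anyNA(newdata)) {
    abort("newdata contains NA; impute first", class = "bcgsleep_parameter_error")
  }
  model <- list(config = object$config, params = object$params)
  fwd <- staging_forward(newdata, model, training = FALSE)
  probs <- fwd$probs
  classes <- object$config$classes
  colnames(probs) <- paste0(".prob_", classes)
  out <- as_tibble(probs)
  out$epoch <- seq_len(nrow(probs)) - 1L
  out$.pred_class <- classes[max.col(probs, ties.method = "first")]
  select(out, "epoch", dplyr::everything())
}

#' @export
print.staging_fit <- function(x, ...) {
  cat(sprintf("<staging_fit: %s, %d parameters, %d training passes>\n",
              x$config$variant, count_parameters(x), nrow(x$log)))
  invisible(x)
}
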