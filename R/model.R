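# The epoch-staging sequence model: two bidirectional LSTM layers feed a
# temporal convolutional network of dilated causal residual blocks, with
# a per-epoch softmax head. Standalone LSTM and TCN variants exist for
# ablation; with the default geometry the three variants carry 469,805,
# 169,093 and 690,885 trainable parameters respectively.

#' Staging-model configuration
#'
#' Geometry of the sequence classifier. Defaults follow the published
#' layout: biLSTM hidden sizes 125 and 100 with dropout 0.2 after each,
#' four residual blocks of two causal dilated convolutions (64 filters,
#' kernel 5, dilation doubling per block), per-channel normalization with
#' scale and offset, ReLU, spatial dropout 0.005, an identity skip with a
#' 1x1 convolution only where channel counts differ, and a 5-class
#' softmax head.
#'
#' @param input_dim Feature dimension F (default 62, the assembled
#'   feature dictionary).
#' @param variant `"lstm_tcn"` (default), `"lstm"` or `"tcn"`.
#' @param bilstm_units Hidden units of the two biLSTM layers.
#' @param bilstm_dropout Dropout after each biLSTM layer.
#' @param n_blocks Number of residual blocks.
#' @param conv_filters,kernel_size Convolution geometry.
#' @param spatial_dropout Channel dropout inside residual blocks.
#' @param n_classes Output classes (default 5).
#' @param classes Class labels.
#' @return A list of class `staging_config`.
#' @export
staging_config <- function(input_dim = 62L,
                           variant = c("lstm_tcn", "lstm", "tcn"),
                           bilstm_units = c(125L, 100L),
                           bilstm_dropout = 0.2,
                           n_blocks = 4L, conv_filters = 64L,
                           kernel_size = 5L, spatial_dropout = 0.005,
                           n_classes = 5L, classes = STAGES_5) {
  variant <- match.arg(variant)
  stopifnot(input_dim > 0, all(bilstm_units > 0), n_blocks > 0,
            conv_filters > 0, kernel_size > 0,
            bilstm_dropout >= 0, bilstm_dropout < 1,
            spatial_dropout >= 0, spatial_dropout < 1,
            n_classes > 0, length(classes) == n_classes)
  structure(list(input_dim = as.integer(input_dim), variant = variant,
                 bilstm_units = as.integer(bilstm_units),
                 bilstm_dropout = bilstm_dropout,
                 n_blocks = as.integer(n_blocks),
                 conv_filters = as.integer(conv_filters),
                 kernel_size = as.integer(kernel_size),
                 spatial_dropout = spatial_dropout,
                 n_classes = as.integer(n_classes), classes = classes),
            class = "staging_config")
}

#' Build an untrained staging model
#'
#' Initializes all parameters (Glorot-uniform weights, zero biases with
#' forget-gate bias 1) for the configured variant. The parameter count is
#' a pure function of the configuration.
#'
#' @param config A [staging_config()].
#' @param seed Integer seed for the initialization RNG.
#' @return A list of class `staging_model` with `config` and `params`.
#' @export
build_staging_model <- function(config = staging_config(), seed = 1L) {
  stopifnot(inherits(config, "staging_config"))
  set.seed(seed)
  params <- list()
  tcn_in <- config$input_dim
  if (config$variant %in% c("lstm_tcn", "lstm")) {
    h1 <- config$bilstm_units[1]; h2 <- config$bilstm_units[2]
    params$lstm <- list(
      list(fw = lstm_init(config$input_dim, h1), bw = lstm_init(config$input_dim, h1)),
      list(fw = lstm_init(2 * h1, h2), bw = lstm_init(2 * h1, h2))
    )
    tcn_in <- 2L * h2
  }
  if (config$variant %in% c("lstm_tcn", "tcn")) {
    blocks <- vector("list", config$n_blocks)
    cin <- tcn_in
    for (b in seq_len(config$n_blocks)) {
      blk <- list(conv1 = conv1d_init(cin, config$conv_filters, config$kernel_size),
                  ln1 = layernorm_init(config$conv_filters),
                  conv2 = conv1d_init(config$conv_filters, config$conv_filters,
                                      config$kernel_size),
                  ln2 = layernorm_init(config$conv_filters))
      if (cin != config$conv_filters) {
        blk$skip <- conv1d_init(cin, config$conv_filters, 1L)
      }
      blocks[[b]] <- blk
      cin <- config$conv_filters
    }
    params$tcn <- blocks
    head_in <- config$conv_filters
  } else {
    head_in <- tcn_in
  }
  params$fc <- fc_init(head_in, config$n_classes)
  structure(list(config = config, params = params, seed = seed),
            class = "staging_model")
}

#' Trainable-parameter count of a model or configuration
#'
#' @param x A `staging_model`, `staging_fit` or [staging_config()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "staging_config")) x <- build_staging_model(x)
  as.integer(tree_count(x$params))
}

#' Receptive field of a stack of dilated causal convolutions
#'
#' `R = (f - 1) (2^K - 1) + 1` epochs for kernel size `f` and `K` stacked
#' convolution layers under dilation doubling. `K` counts individual
#' convolution layers; with two convolutions per residual block and
#' dilation doubling per *block* (as built here), pass the total layer
#' count for the formula's idealized bound, or the block count for the
#' per-block dilation schedule.
#'
#' @param f Kernel (filter) size, >= 1.
#' @param K Number of stacked dilated convolution layers, >= 1.
#' @return Receptive field in epochs.
#' @export
receptive_field <- function(f, K) {
  stopifnot(f >= 1, K >= 1)
  (f - 1) * (2^K - 1) + 1
}

block_dilation <- function(b) 2L^(b - 1L)

## ---- full forward / backward -----------------------------------------

staging_forward <- function(X, model, training = FALSE) {
  cfg <- model$config
  p <- model$params
  cache <- list()
  H <- X
  if (!is.null(p$lstm)) {
    cache$lstm <- vector("list", length(p$lstm))
    for (l in seq_along(p$lstm)) {
      fw <- bilstm_forward(H, p$lstm[[l]])
      mask <- if (training) dropout_mask(nrow(fw$H), ncol(fw$H), cfg$bilstm_dropout)
              else matrix(1, 1, 1)
      Hn <- if (training) fw$H * mask else fw$H
      cache$lstm[[l]] <- list(cache = fw$cache, mask = mask)
      H <- Hn
    }
  }
  if (!is.null(p$tcn)) {
    cache$tcn <- vector("list", length(p$tcn))
    for (b in seq_along(p$tcn)) {
      blk <- p$tcn[[b]]
      d <- block_dilation(b)
      c1 <- conv1d_forward(H, blk$conv1, d)
      n1 <- layernorm_forward(c1$Y, blk$ln1)
      r1 <- relu_forward(n1$Y)
      m1 <- if (training) spatial_dropout_mask(nrow(r1$Y), ncol(r1$Y),
                                               cfg$spatial_dropout)
            else matrix(1, 1, 1)
      h1 <- if (training) r1$Y * m1 else r1$Y
      c2 <- conv1d_forward(h1, blk$conv2, d)
      n2 <- layernorm_forward(c2$Y, blk$ln2)
      r2 <- relu_forward(n2$Y)
      m2 <- if (training) spatial_dropout_mask(nrow(r2$Y), ncol(r2$Y),
                                               cfg$spatial_dropout)
            else matrix(1, 1, 1)
      h2 <- if (training) r2$Y * m2 else r2$Y
      if (!is.null(blk$skip)) {
        sk <- conv1d_forward(H, blk$skip, 1L)
        skip_out <- sk$Y
        skip_cache <- sk$cache
      } else {
        skip_out <- H
        skip_cache <- NULL
      }
      out <- h2 + skip_out
      cache$tcn[[b]] <- list(c1 = c1$cache, n1 = n1$cache, r1 = r1$cache,
                             m1 = m1, c2 = c2$cache, n2 = n2$cache,
                             r2 = r2$cache, m2 = m2, skip = skip_cache,
                             training = training)
      H <- out
    }
  }
  fc <- fc_forward(H, p$fc)
  cache$fc <- fc$cache
  list(logits = fc$Y, probs = softmax_rows(fc$Y), cache = cache)
}

staging_backward <- function(dlogits, fwd, model) {
  p <- model$params
  grads <- list()
  bfc <- fc_backward(dlogits, fwd$cache$fc, p$fc)
  dH <- bfc$dX
  if (!is.null(p$tcn)) {
    gt <- vector("list", length(p$tcn))
    for (b in rev(seq_along(p$tcn))) {
      blk <- p$tcn[[b]]
      cc <- fwd$cache$tcn[[b]]
      d_skip_in <- dH
      dh2 <- if (cc$training) dH * cc$m2 else dH
      dr2 <- relu_backward(dh2, cc$r2)
      bn2 <- layernorm_backward(dr2, cc$n2, blk$ln2)
      bc2 <- conv1d_backward(bn2$dX, cc$c2, blk$conv2)
      dh1 <- if (cc$training) bc2$dX * cc$m1 else bc2$dX
      dr1 <- relu_backward(dh1, cc$r1)
      bn1 <- layernorm_backward(dr1, cc$n1, blk$ln1)
      bc1 <- conv1d_backward(bn1$dX, cc$c1, blk$conv1)
      g <- list(conv1 = bc1$grads, ln1 = bn1$grads,
                conv2 = bc2$grads, ln2 = bn2$grads)
      if (!is.null(blk$skip)) {
        bsk <- conv1d_backward(d_skip_in, cc$skip, blk$skip)
        g$skip <- bsk$grads
        dH <- bc1$dX + bsk$dX
      } else {
        dH <- bc1$dX + d_skip_in
      }
      gt[[b]] <- g
    }
    grads$tcn <- gt
  }
  if (!is.null(p$lstm)) {
    gl <- vector("list", length(p$lstm))
    for (l in rev(seq_along(p$lstm))) {
      cc <- fwd$cache$lstm[[l]]
      dHl <- if (is.matrix(cc$mask) && length(cc$mask) > 1) dH * cc$mask else dH
      bb <- bilstm_backward(dHl, cc$cache, p$lstm[[l]])
      gl[[l]] <- bb$grads
      dH <- bb$dX
    }
    grads$lstm <- gl
  }
  # order grads to mirror params exactly
  out <- list()
  if (!is.null(p$lstm)) out$lstm <- grads$lstm
  if (!is.null(p$tcn)) out$tcn <- grads$tcn
  out$fc <- bfc$grads
  out
}
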