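tiny_config <- function(variant = "lstm_tcn") {
  staging_config(input_dim = 3L, variant = variant,
                 bilstm_units = c(4L, 3L), n_blocks = 2L,
                 conv_filters = 4L, kernel_size = 2L,
                 bilstm_dropout = 0, spatial_dropout = 0,
                 n_classes = 3L, classes = c("A", "B", "C"))
}

test_that("receptive field follows the dilation-doubling formula", {
  expect_equal(receptive_field(1, 6), 1)
  expect_equal(receptive_field(5, 2), 13)
  expect_equal(receptive_field(5, 8), 1021)
})

test_that("parameter count is a pure function of the configuration", {
  cfg <- tiny_config()
  expect_identical(count_parameters(build_staging_model(cfg, seed = 1)),
                   count_parameters(build_staging_model(cfg, seed = 99)))
  # closed form for the tiny geometry: biLSTM(4)+biLSTM(3) over 3 inputs,
  # 2 blocks of 2 convs (4 filters, kernel 2) with layer norms, skip 1x1
  # in block 1, FC(4 -> 3)
  lstm1 <- 2 * (4 * 4 * (3 + 4) + 4 * 4)
  lstm2 <- 2 * (4 * 3 * (8 + 3) + 4 * 3)
  blk1 <- (2 * 6 * 4 + 4) + 8 + (2 * 4 * 4 + 4) + 8 + (6 * 4 + 4)
  blk2 <- 2 * (2 * 4 * 4 + 4) + 16
  fc <- 4 * 3 + 3
  expect_equal(count_parameters(cfg), lstm1 + lstm2 + blk1 + blk2 + fc)
})

test_that("backpropagation matches finite-difference gradients", {
  ns <- asNamespace("bcgsleep")
  set.seed(42)
  for (variant in c("lstm", "tcn", "lstm_tcn")) {
    model <- build_staging_model(tiny_config(variant), seed = 7)
    X <- matrix(rnorm(8 * 3), 8, 3)
    y <- sample(1:3, 8, TRUE)
    w <- c(1.2, 0.8, 1.0)
    loss_fn <- function(params) {
      m <- model; m$params <- params
      fwd <- ns$staging_forward(X, m, training = FALSE)
      ns$weighted_ce(fwd$logits, y, w)$loss
    }
    fwd <- ns$staging_forward(X, model, training = FALSE)
    ce <- ns$weighted_ce(fwd$logits, y, w)
    grads <- ns$staging_backward(ce$dlogits, fwd, model)
    flat_paths <- function(tree, prefix = integer()) {
      if (is.list(tree)) {
        unlist(lapply(seq_along(tree),
                      function(i) flat_paths(tree[[i]], c(prefix, i))),
               recursive = FALSE)
      } else list(prefix)
    }
    assign_leaf <- function(tree, path, idx, val) {
      if (length(path) == 0) { tree[idx] <- val; return(tree) }
      tree[[path[1]]] <- assign_leaf(tree[[path[1]]], path[-1], idx, val)
      tree
    }
    for (p in flat_paths(model$params)) {
      leaf <- Reduce(function(x, i) x[[i]], p, model$params)
      gleaf <- Reduce(function(x, i) x[[i]], p, grads)
      expect_identical(length(leaf), length(gleaf))
      ii <- sample(length(leaf), 1)
      eps <- 1e-5
      num <- (loss_fn(assign_leaf(model$params, p, ii, leaf[ii] + eps)) -
              loss_fn(assign_leaf(model$params, p, ii, leaf[ii] - eps))) / (2 * eps)
      expect_equal(gleaf[ii], num, tolerance = 1e-4)
    }
  }
})

test_that("softmax output is a probability simplex per epoch", {
  set.seed(43)
  x <- lapply(1:2, function(i) matrix(rnorm(20 * 3), 20, 3))
  y <- lapply(1:2, function(i) sample(c("A", "B", "C"), 20, TRUE))
  fit <- train_staging_model(x, y, tiny_config(),
                             staging_hyper(max_passes = 2), seed = 3)
  pr <- predict(fit, x[[1]])
  probs <- as.matrix(pr[, paste0(".prob_", c("A", "B", "C"))])
  expect_equal(rowSums(probs), rep(1, 20), tolerance = 1e-6)
  expect_true(all(probs >= 0))
  # duplicated input -> identical predictions
  expect_identical(predict(fit, x[[1]]), predict(fit, x[[1]]))
})

test_that("the TCN path is causal", {
  set.seed(44)
  cfg <- tiny_config("tcn")
  model <- build_staging_model(cfg, seed = 5)
  ns <- asNamespace("bcgsleep")
  X <- matrix(rnorm(30 * 3), 30, 3)
  base <- ns$staging_forward(X, model, training = FALSE)$probs
  k <- 12
  X2 <- X
  X2[(k + 2):30, ] <- rnorm(length(X2[(k + 2):30, ]))
  pert <- ns$staging_forward(X2, model, training = FALSE)$probs
  expect_equal(base[1:(k + 1), ], pert[1:(k + 1), ], tolerance = 1e-12)
})

test_that("training is deterministic and reduces loss on separable data", {
  set.seed(45)
  make_seq <- function(seed) {
    set.seed(seed)
    y <- sample(c("A", "B", "C"), 40, TRUE)
    centers <- rbind(A = c(3, 0, 0), B = c(0, 3, 0), C = c(0, 0, 3))
    x <- centers[y, ] + matrix(rnorm(40 * 3, 0, 0.3), 40, 3)
    list(x = x, y = y)
  }
  seqs <- lapply(1:2, function(i) make_seq(100 + i))
  x <- lapply(seqs, `[[`, "x"); y <- lapply(seqs, `[[`, "y")
  fit1 <- train_staging_model(x, y, tiny_config(),
                              staging_hyper(max_passes = 5, patience = 99),
                              seed = 9)
  log1 <- tidy(fit1)
  expect_true(all(diff(log1$train_loss[1:5]) < 0))
  fit2 <- train_staging_model(x, y, tiny_config(),
                              staging_hyper(max_passes = 5, patience = 99),
                              seed = 9)
  expect_identical(tidy(fit1), tidy(fit2))
  expect_identical(fit1$params, fit2$params)
  # label/row mismatch refused
  expect_error(train_staging_model(list(x[[1]]), list(y[[1]][-1]), tiny_config()),
               class = "bcgsleep_parameter_error")
  # absent class warns
  y_two <- lapply(y, function(v) replace(v, v == "C", "A"))
  expect_warning(train_staging_model(x, y_two, tiny_config(),
                                     staging_hyper(max_passes = 1), seed = 1),
                 "absent")
})

test_that("prediction refuses mismatched input width", {
  set.seed(46)
  fit <- train_staging_model(list(matrix(rnorm(30), 10, 3)),
                             list(sample(c("A", "B", "C"), 10, TRUE)),
                             tiny_config(), staging_hyper(max_passes = 1),
                             seed = 1)
  expect_error(predict(fit, matrix(0, 5, 4)), class = "bcgsleep_parameter_error")
  expect_error(predict(fit, matrix(NA_real_, 5, 3)), class = "bcgsleep_parameter_error")
})
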