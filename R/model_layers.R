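# Differentiable layers for the staging network, implemented directly on
# base-R matrix algebra: bidirectional LSTM, causal dilated 1-D
# convolution, per-channel (layer) normalization, ReLU, spatial dropout
# and a per-timestep linear/softmax head. Every backward pass is the
# hand-derived adjoint of its forward and is validated against
# finite-difference gradients in the test suite.
#
# Convention: sequences are time-major matrices (T x channels).

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

## ---- LSTM (one direction) --------------------------------------------

lstm_init <- function(input_dim, hidden) {
  list(W = glorot(4 * hidden, input_dim),
       U = glorot(4 * hidden, hidden),
       b = c(rep(0, hidden), rep(1, hidden), rep(0, 2 * hidden)))  # forget bias 1
}

lstm_dir_forward <- function(X, p) {
  H <- nrow(p$U) / 4
  T_ <- nrow(X)
  Zin <- X %*% t(p$W)
  I <- F_ <- G <- O <- C <- TC <- Hout <- Hprev <- Cprev <- matrix(0, T_, H)
  h <- numeric(H); cc <- numeric(H)
  idx <- list(1:H, (H + 1):(2 * H), (2 * H + 1):(3 * H), (3 * H + 1):(4 * H))
  for (t in seq_len(T_)) {
    Hprev[t, ] <- h; Cprev[t, ] <- cc
    z <- Zin[t, ] + as.numeric(p$U %*% h) + p$b
    i <- sigmoid(z[idx[[1]]]); f <- sigmoid(z[idx[[2]]])
    g <- tanh(z[idx[[3]]]); o <- sigmoid(z[idx[[4]]])
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h <- o * tc
    I[t, ] <- i; F_[t, ] <- f; G[t, ] <- g; O[t, ] <- o
    C[t, ] <- cc; TC[t, ] <- tc; Hout[t, ] <- h
  }
  list(H = Hout, cache = list(X = X, I = I, F = F_, G = G, O = O, C = C,
                              TC = TC, Hprev = Hprev, Cprev = Cprev))
}

lstm_dir_backward <- function(dH, cache, p) {
  T_ <- nrow(dH); H <- ncol(dH)
  dZ <- matrix(0, T_, 4 * H)
  dh_next <- numeric(H); dc_next <- numeric(H)
  for (t in rev(seq_len(T_))) {
    dh <- dH[t, ] + dh_next
    do_ <- dh * cache$TC[t, ]
    dc <- dc_next + dh * cache$O[t, ] * (1 - cache$TC[t, ]^2)
    di <- dc * cache$G[t, ]
    df <- dc * cache$Cprev[t, ]
    dg <- dc * cache$I[t, ]
    i <- cache$I[t, ]; f <- cache$F[t, ]; g <- cache$G[t, ]; o <- cache$O[t, ]
    dz <- c(di * i * (1 - i), df * f * (1 - f), dg * (1 - g^2), do_ * o * (1 - o))
    dZ[t, ] <- dz
    dh_next <- as.numeric(t(p$U) %*% dz)
    dc_next <- dc * f
  }
  list(dX = dZ %*% p$W,
       grads = list(W = t(dZ) %*% cache$X,
                    U = t(dZ) %*% cache$Hprev,
                    b = colSums(dZ)))
}

bilstm_forward <- function(X, p) {
  fw <- lstm_dir_forward(X, p$fw)
  rev_idx <- rev(seq_len(nrow(X)))
  bw <- lstm_dir_forward(X[rev_idx, , drop = FALSE], p$bw)
  list(H = cbind(fw$H, bw$H[rev_idx, , drop = FALSE]),
       cache = list(fw = fw$cache, bw = bw$cache, rev_idx = rev_idx))
}

bilstm_backward <- function(dH, cache, p) {
  H <- ncol(dH) / 2
  rev_idx <- cache$rev_idx
  bfw <- lstm_dir_backward(dH[, 1:H, drop = FALSE], cache$fw, p$fw)
  bbw <- lstm_dir_backward(dH[rev_idx, (H + 1):(2 * H), drop = FALSE],
                           cache$bw, p$bw)
  list(dX = bfw$dX + bbw$dX[rev_idx, , drop = FALSE],
       grads = list(fw = bfw$grads, bw = bbw$grads))
}

## ---- Causal dilated conv ---------------------------------------------

conv1d_init <- function(c_in, c_out, kernel) {
  list(W = map(seq_len(kernel), ~ glorot(c_in, c_out) / sqrt(kernel)),
       b = numeric(c_out))
}

shift_down <- function(X, s) {
  if (s == 0) return(X)
  T_ <- nrow(X)
  if (s >= T_) return(matrix(0, T_, ncol(X)))
  rbind(matrix(0, s, ncol(X)), X[1:(T_ - s), , drop = FALSE])
}

shift_up <- function(X, s) {
  if (s == 0) return(X)
  T_ <- nrow(X)
  if (s >= T_) return(matrix(0, T_, ncol(X)))
  rbind(X[(s + 1):T_, , drop = FALSE], matrix(0, s, ncol(X)))
}

conv1d_forward <- function(X, p, dilation) {
  T_ <- nrow(X)
  Y <- matrix(p$b, T_, length(p$b), byrow = TRUE)
  for (j in seq_along(p$W)) {
    Y <- Y + shift_down(X, (j - 1) * dilation) %*% p$W[[j]]
  }
  list(Y = Y, cache = list(X = X, dilation = dilation))
}

conv1d_backward <- function(dY, cache, p) {
  dX <- matrix(0, nrow(dY), nrow(p$W[[1]]))
  gW <- vector("list", length(p$W))
  for (j in seq_along(p$W)) {
    s <- (j - 1) * cache$dilation
    Xs <- shift_down(cache$X, s)
    gW[[j]] <- t(Xs) %*% dY
    dX <- dX + shift_up(dY %*% t(p$W[[j]]), s)
  }
  list(dX = dX, grads = list(W = gW, b = colSums(dY)))
}

## ---- Layer (per-channel) normalization --------------------------------

LN_EPS <- 1e-5

layernorm_init <- function(channels) list(gamma = rep(1, channels),
                                          beta = numeric(channels))

layernorm_forward <- function(X, p) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  Y <- sweep(xhat, 2, p$gamma, "*")
  Y <- sweep(Y, 2, p$beta, "+")
  list(Y = Y, cache = list(xhat = xhat, inv = inv))
}

layernorm_backward <- function(dY, cache, p) {
  dxhat <- sweep(dY, 2, p$gamma, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- (dxhat - m1 - cache$xhat * m2) * cache$inv
  list(dX = dX, grads = list(gamma = colSums(dY * cache$xhat),
                             beta = colSums(dY)))
}

## ---- Simple activations / dropout ------------------------------------

relu_forward <- function(X) list(Y = pmax(X, 0), cache = X > 0)
relu_backward <- function(dY, cache) dY * cache

# element dropout (between LSTM layers)
dropout_mask <- function(dim_r, dim_c, p) {
  if (p <= 0) return(matrix(1, dim_r, dim_c))
  matrix((runif(dim_r * dim_c) >= p) / (1 - p), dim_r, dim_c)
}

# spatial (channel) dropout for conv stacks: drops whole channels
spatial_dropout_mask <- function(dim_r, dim_c, p) {
  if (p <= 0) return(matrix(1, dim_r, dim_c))
  ch <- (runif(dim_c) >= p) / (1 - p)
  matrix(ch, dim_r, dim_c, byrow = TRUE)
}

## ---- Head --------------------------------------------------------------

fc_init <- function(c_in, c_out) list(W = glorot(c_in, c_out), b = numeric(c_out))

fc_forward <- function(X, p) {
  list(Y = sweep(X %*% p$W, 2, p$b, "+"), cache = X)
}

fc_backward <- function(dY, cache, p) {
  list(dX = dY %*% t(p$W),
       grads = list(W = t(cache) %*% dY, b = colSums(dY)))
}

softmax_rows <- function(L) {
  m <- apply(L, 1, max)
  e <- exp(L - m)
  e / rowSums(e)
}

# Class-weighted cross entropy over a sequence. y: integer labels 1..K,
# possibly NA (excluded); w: per-class weights. Returns loss and dlogits.
weighted_ce <- function(logits, y, w) {
  P <- softmax_rows(logits)
  keep <- !is.na(y)
  wy <- ifelse(keep, w[y], 0)
  denom <- sum(wy)
  onehot <- matrix(0, nrow(logits), ncol(logits))
  onehot[cbind(which(keep), y[keep])] <- 1
  loss <- -sum(wy[keep] * log(pmax(P[cbind(which(keep), y[keep])], 1e-12))) / denom
  dL <- (P - onehot) * wy / denom
  list(loss = loss, dlogits = dL, probs = P)
}

## ---- Parameter-tree utilities -----------------------------------------

# Apply f elementwise over parallel nested lists of numeric arrays.
tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1]])) {
    out <- vector("list", length(trees[[1]]))
    names(out) <- names(trees[[1]])
    for (i in seq_along(out)) {
      out[[i]] <- do.call(tree_map, c(list(f), map(trees, ~ .x[[i]])))
    }
    out
  } else {
    do.call(f, trees)
  }
}

tree_sum <- function(tree, f = identity) {
  if (is.list(tree)) sum(map_dbl(tree, tree_sum, f = f)) else sum(f(tree))
}

tree_count <- function(tree) {
  if (is.list(tree)) sum(map_dbl(tree, tree_count)) else length(tree)
}
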