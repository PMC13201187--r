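# Literal brute-force reference implementations, kept deliberately
# independent of the package's vectorized code paths: plain loops that
# transcribe each definition directly.

bf_autocov <- function(y, k) {
  T_ <- length(y)
  ybar <- mean(y)
  s <- 0
  for (t in seq_len(T_ - k)) s <- s + (y[t] - ybar) * (y[t + k] - ybar)
  s / T_
}

bf_autocorr <- function(y, k) bf_autocov(y, k) / bf_autocov(y, 0)

bf_sampen <- function(x, m, r) {
  n <- length(x)
  count <- function(mm) {
    tot <- 0L
    for (i in 1:(n - m)) {
      for (j in 1:(n - m)) {
        if (i == j) next
        d <- 0
        for (k in 0:(mm - 1)) d <- max(d, abs(x[i + k] - x[j + k]))
        if (d <= r) tot <- tot + 1L
      }
    }
    tot / 2
  }
  -log(count(m + 1) / count(m))
}

bf_renyi <- function(jj, alpha, m, sigma) {
  n <- length(jj) - m + 1
  rho <- numeric(n)
  for (i in 1:n) {
    for (j in 1:n) {
      d <- 0
      for (k in 0:(m - 1)) d <- d + sqrt((jj[i + k] - jj[j + k])^2)
      rho[i] <- rho[i] + exp(-d^2 / (2 * sigma^2))
    }
    rho[i] <- rho[i] / (sigma * sqrt(2 * pi))
  }
  rho <- rho / sum(rho)
  if (abs(alpha - 1) < 1e-12) -sum(rho * log2(rho))
  else log2(sum(rho^alpha)) / (1 - alpha)
}

bf_poincare_sd <- function(jj) {
  n <- length(jj)
  d <- s <- numeric(n - 1)
  for (i in 1:(n - 1)) {
    d[i] <- jj[i + 1] - jj[i]
    s[i] <- jj[i + 1] + jj[i]
  }
  c(sd1 = sd(d) / sqrt(2), sd2 = sd(s) / sqrt(2))
}

bf_porta <- function(jj) {
  below <- 0L; off <- 0L
  for (i in 1:(length(jj) - 1)) {
    if (jj[i + 1] < jj[i]) below <- below + 1L
    if (jj[i + 1] != jj[i]) off <- off + 1L
  }
  100 * below / off
}

# small deterministic session builder used across test files
toy_session <- function(duration_s = 600, seed = 5, audio = FALSE,
                        preset = "default") {
  synth_session(synth_config(preset = preset, duration_s = duration_s),
                seed = seed, audio = audio)
}
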