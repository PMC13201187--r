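# Nonlinear complexity features: Renyi entropy of a kernel density over
# embedded beat subsequences, sample/approximate entropy, and detrended
# fluctuation analysis.

embed_rows <- function(x, m) {
  n <- length(x) - m + 1L
  mat <- matrix(0, n, m)
  for (k in seq_len(m)) mat[, k] <- x[k:(k + n - 1L)]
  mat
}

# L1 distances between all pairs of embedded subsequences: the sum of the
# per-coordinate (1-D Euclidean) distances over the embedding window.
embedded_l1_dist <- function(emb) {
  n <- nrow(emb)
  dmat <- matrix(0, n, n)
  for (k in seq_len(ncol(emb))) {
    dmat <- dmat + abs(outer(emb[, k], emb[, k], "-"))
  }
  dmat
}

#' Renyi entropy of the beat-interval series
#'
#' Order-alpha entropy of a density over embedded JJ subsequences. Each
#' length-`embed_m` subsequence gets a Gaussian-kernel similarity mass
#' `rho_i` proportional to `sum_j exp(-dist_ij^2 / (2 sigma^2))`, where
#' `dist_ij` is the summed coordinate-wise distance between subsequences;
#' the masses are normalized to sum to one and
#' `H_alpha = log2(sum(rho^alpha)) / (1 - alpha)` (bits). `alpha = 1`
#' is computed as the Shannon limit `-sum(rho * log2(rho))`. A uniform
#' density over n subsequences gives `log2(n)` for every order, and
#' `H_alpha` is non-increasing in alpha.
#'
#' @param jj Numeric vector of valid JJ intervals (ms).
#' @param alpha Entropy order(s), each > 0.
#' @param embed_m Embedding length in beats (default 2).
#' @param sigma Kernel dispersion; default is the SD of the embedded
#'   pairwise distances. Must be positive.
#' @return Tibble `alpha, h_bits, ok`.
#' @export
renyi_entropy <- function(jj, alpha = c(0.25, 1, 2, 5), embed_m = 2,
                          sigma = NULL) {
  if (any(alpha <= 0)) abort("alpha must be positive", class = "bcgsleep_parameter_error")
  jj <- jj[is.finite(jj)]
  if (length(jj) <= embed_m) {
    return(tibble(alpha = alpha, h_bits = NA_real_, ok = FALSE))
  }
  emb <- embed_rows(jj, embed_m)
  dmat <- embedded_l1_dist(emb)
  if (is.null(sigma)) sigma <- sd(dmat[upper.tri(dmat)])
  if (!is.finite(sigma) || sigma <= 0) {
    return(tibble(alpha = alpha, h_bits = NA_real_, ok = FALSE))
  }
  rho <- rowSums(exp(-dmat^2 / (2 * sigma^2))) / (sigma * sqrt(2 * pi))
  rho <- rho / sum(rho)
  h <- map_dbl(alpha, function(a) {
    if (abs(a - 1) < 1e-12) {
      -sum(rho * log2(rho))
    } else {
      log2(sum(rho^a)) / (1 - a)
    }
  })
  tibble(alpha = alpha, h_bits = h, ok = TRUE)
}

chebyshev_match_counts <- function(x, m, r) {
  emb <- embed_rows(x, m)
  n <- nrow(emb)
  dmat <- matrix(0, n, n)
  for (k in seq_len(ncol(emb))) {
    dmat <- pmax(dmat, abs(outer(emb[, k], emb[, k], "-")))
  }
  dmat <= r
}

#' Sample and approximate entropy
#'
#' Standard SampEn and ApEn with embedding dimension `m` and tolerance
#' `r_frac * SD(jj)` under the Chebyshev norm. SampEn excludes
#' self-matches and is flagged infinite when no template pair matches at
#' `m + 1`; ApEn includes self-matches as usual.
#'
#' @param jj Numeric vector of valid JJ intervals (ms), length >= 10 * m.
#' @param m Embedding dimension (default 2).
#' @param r_frac Tolerance as a fraction of the series SD (default 0.2).
#' @return Tibble `sampen, apen, ok`.
#' @export
sample_approx_entropy <- function(jj, m = 2, r_frac = 0.2) {
  jj <- jj[is.finite(jj)]
  n <- length(jj)
  if (n < 10 * m || sd(jj) == 0 && n >= 10 * m) {
    if (n >= 10 * m && sd(jj) == 0) {
      # constant series: every template matches at every length
      return(tibble(sampen = 0, apen = 0, ok = TRUE))
    }
    return(tibble(sampen = NA_real_, apen = NA_real_, ok = FALSE))
  }
  r <- r_frac * sd(jj)
  # SampEn: count pairs over the common n - m templates at both lengths
  match_m <- chebyshev_match_counts(jj, m, r)
  match_m1 <- chebyshev_match_counts(jj, m + 1, r)
  nt <- n - m  # templates comparable at length m+1
  mm <- match_m[seq_len(nt), seq_len(nt), drop = FALSE]
  b_count <- (sum(mm) - nt) / 2
  a_count <- (sum(match_m1) - nrow(match_m1)) / 2
  sampen <- if (a_count > 0 && b_count > 0) -log(a_count / b_count) else Inf
  # ApEn: self-matches included
  phi <- function(mm_mat) {
    ci <- rowSums(mm_mat) / ncol(mm_mat)
    mean(log(ci))
  }
  apen <- phi(match_m) - phi(match_m1)
  tibble(sampen = sampen, apen = apen, ok = TRUE)
}

#' Detrended fluctuation analysis
#'
#' Integrates the mean-removed series, splits the profile into
#' non-overlapping boxes, removes a least-squares line per box and takes
#' the RMS residual `F(n)`; the scaling exponents are the log-log slopes
#' of `F(n)` over the short-range (`alpha1`) and long-range (`alpha2`)
#' box sizes. White noise gives alpha near 0.5, a random walk near 1.5.
#'
#' @param jj Numeric vector (beats).
#' @param range1,range2 Box-size ranges in beats (defaults 4-16 and
#'   16-64).
#' @return Tibble `dfa_alpha1, dfa_alpha2, ok`; `dfa_alpha2` is NA when
#'   the series is shorter than four times the largest long-range box.
#' @export
dfa <- function(jj, range1 = c(4, 16), range2 = c(16, 64)) {
  jj <- jj[is.finite(jj)]
  n <- length(jj)
  if (n < 4 * range1[2]) {
    return(tibble(dfa_alpha1 = NA_real_, dfa_alpha2 = NA_real_, ok = FALSE))
  }
  prof <- cumsum(jj - mean(jj))
  fluct <- function(nb) {
    k <- n %/% nb
    idx <- seq_len(k * nb)
    segs <- matrix(prof[idx], nrow = nb)
    i <- seq_len(nb)
    ss <- 0
    for (j in seq_len(k)) {
      res <- stats::lm.fit(cbind(1, i), segs[, j])$residuals
      ss <- ss + sum(res^2)
    }
    sqrt(ss / (k * nb))
  }
  slope_over <- function(rg) {
    sizes <- unique(round(exp(seq(log(rg[1]), log(rg[2]), length.out = 8))))
    sizes <- sizes[sizes >= 4 & sizes <= n %/% 4]
    if (length(sizes) < 3) return(NA_real_)
    f <- map_dbl(sizes, fluct)
    keep <- f > 0
    if (sum(keep) < 3) return(NA_real_)
    unname(coef(lm(log(f[keep]) ~ log(sizes[keep])))[2])
  }
  tibble(dfa_alpha1 = slope_over(range1), dfa_alpha2 = slope_over(range2),
         ok = TRUE)
}
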