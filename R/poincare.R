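# Poincare-plot geometry, asymmetry indices about the line of identity,
# and sequential trend analysis of successive interval changes.

#' Poincare plot dispersion (SD1/SD2)
#'
#' Width and length of the scatter of consecutive intervals
#' `(JJ_i, JJ_{i+1})`: `sd1 = SD(JJ_{i+1} - JJ_i) / sqrt(2)` (dispersion
#' perpendicular to the line of identity, short-term variability) and
#' `sd2 = SD(JJ_{i+1} + JJ_i) / sqrt(2)` (along it, long-term
#' variability).
#'
#' @param jj Numeric vector of valid JJ intervals (ms), length >= 3.
#' @return Tibble `sd1, sd2, sd1_sd2_ratio, ok`.
#' @export
poincare_sd <- function(jj) {
  jj <- jj[is.finite(jj)]
  if (length(jj) < 3) {
    return(tibble(sd1 = NA_real_, sd2 = NA_real_, sd1_sd2_ratio = NA_real_,
                  ok = FALSE))
  }
  x <- jj[-length(jj)]; y <- jj[-1]
  sd1 <- sd(y - x) / sqrt(2)
  sd2 <- sd(y + x) / sqrt(2)
  tibble(sd1 = sd1, sd2 = sd2,
         sd1_sd2_ratio = if (sd2 > 0) sd1 / sd2 else NA_real_, ok = TRUE)
}

#' Poincare asymmetry indices
#'
#' Quantify the imbalance of the Poincare scatter about the line of
#' identity (LOI, `JJ_{i+1} = JJ_i`). Points exactly on the LOI carry no
#' sign information and are excluded from the Porta/Guzik denominators.
#'
#' * `porta_pct`: percentage of off-LOI points below the LOI
#'   (decelerations vs accelerations by count).
#' * `guzik_pct`: percentage of the total LOI distance contributed by
#'   points above the LOI (`d_i = |JJ_{i+1} - JJ_i| / sqrt(2)`).
#' * `ehler_index`: skewness-like statistic of successive differences,
#'   `sum(d^3) / sum(d^2)^(3/2)`.
#' * `phase_index`: mean angular deviation from 45 degrees
#'   (`atan(JJ_{i+1}/JJ_i) - 45`, degrees) over above-LOI points.
#' * `area_index`: percentage of the cumulative circular-sector area
#'   (`r_i^2 * |theta_i| / 2`) contributed by above-LOI points.
#'
#' @param jj Numeric vector of valid JJ intervals (ms), length >= 3.
#' @return Tibble `porta_pct, guzik_pct, ehler_index, phase_index,
#'   area_index, ok`; `ok = FALSE` when every point lies on the LOI.
#' @export
poincare_asymmetry <- function(jj) {
  jj <- jj[is.finite(jj)]
  empty <- tibble(porta_pct = NA_real_, guzik_pct = NA_real_,
                  ehler_index = NA_real_, phase_index = NA_real_,
                  area_index = NA_real_, ok = FALSE)
  if (length(jj) < 3) return(empty)
  x <- jj[-length(jj)]; y <- jj[-1]
  d <- y - x
  off <- d != 0
  if (!any(off)) return(empty)
  below <- d < 0
  above <- d > 0
  porta <- 100 * sum(below) / sum(off)
  dist_loi <- abs(d) / sqrt(2)
  guzik <- 100 * sum(dist_loi[above]) / sum(dist_loi[off])
  ehler <- sum(d^3) / (sum(d^2))^(3 / 2)
  theta <- atan2(y, x) * 180 / pi - 45
  phase <- if (any(above)) mean(theta[above]) else NA_real_
  r2 <- x^2 + y^2
  sector <- r2 * abs(theta * pi / 180) / 2
  area <- 100 * sum(sector[above]) / sum(sector[off])
  tibble(porta_pct = porta, guzik_pct = guzik, ehler_index = ehler,
         phase_index = phase, area_index = area, ok = TRUE)
}

#' Sequential trend analysis of interval changes
#'
#' Maps consecutive successive differences into the plane
#' `(dJJ_n, dJJ_{n+1})`; the quadrant pattern separates sustained
#' decelerations (Q1: +,+), sustained accelerations (Q3: -,-) and
#' alternations (Q2: -,+ and Q4: +,-). Each populated quadrant is
#' summarized by the mean radial distance
#' `mean(sqrt(a_n^2 + a_{n+1}^2))` of its points and its occupancy
#' fraction. Pairs with a zero component sit on a quadrant boundary and
#' are excluded from occupancy.
#'
#' @param jj Numeric vector of valid JJ intervals (ms), length >= 4.
#' @return Tibble `sta_d_q1..q4`, `sta_occ_q1..q4`, `ok`; distances are 0
#'   with occupancy 0 for empty quadrants; `ok = FALSE` when no pair is
#'   strictly inside a quadrant (e.g. a constant series).
#' @export
sta_features <- function(jj) {
  jj <- jj[is.finite(jj)]
  empty <- tibble(sta_d_q1 = NA_real_, sta_d_q2 = NA_real_,
                  sta_d_q3 = NA_real_, sta_d_q4 = NA_real_,
                  sta_occ_q1 = NA_real_, sta_occ_q2 = NA_real_,
                  sta_occ_q3 = NA_real_, sta_occ_q4 = NA_real_, ok = FALSE)
  if (length(jj) < 4) return(empty)
  dd <- diff(jj)
  a <- dd[-length(dd)]; b <- dd[-1]
  inside <- a != 0 & b != 0
  if (!any(inside)) return(empty)
  a <- a[inside]; b <- b[inside]
  quad <- ifelse(a > 0 & b > 0, 1L,
          ifelse(a < 0 & b > 0, 2L,
          ifelse(a < 0 & b < 0, 3L, 4L)))
  r <- sqrt(a^2 + b^2)
  dist <- occ <- numeric(4)
  for (q in 1:4) {
    sel <- quad == q
    occ[q] <- mean(sel)
    dist[q] <- if (any(sel)) mean(r[sel]) else 0
  }
  tibble(sta_d_q1 = dist[1], sta_d_q2 = dist[2], sta_d_q3 = dist[3],
         sta_d_q4 = dist[4], sta_occ_q1 = occ[1], sta_occ_q2 = occ[2],
         sta_occ_q3 = occ[3], sta_occ_q4 = occ[4], ok = TRUE)
}
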