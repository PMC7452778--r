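# Unimodality test for the F_ST distribution. The statistic measures how
# far the empirical CDF is from the nearest unimodal (convex-then-concave)
# CDF, using the greatest-convex-minorant / least-concave-majorant
# construction: for a split point m the best convex fit to the ECDF left
# of x_m is its greatest convex minorant (GCM) shifted up by half its
# maximal deviation, and symmetrically the least concave majorant (LCM) on
# the right; the statistic is
#
#   dip = min over m of max(dev_GCM(1..m), dev_LCM(m..n)) / 2.
#
# dev_GCM(1..m) is non-decreasing in m (adding points on the right can
# only lower the prefix hull) and dev_LCM(m..n) is non-increasing, so the
# minimiser is located by binary search on their crossing. Significance is
# calibrated by a uniform bootstrap -- the classical reference null -- with
# the same statistic.

# Max deviation of the ECDF above the greatest convex minorant of its
# first m points. The hull is the lower convex hull of (x_i, (i-1)/n)
# (the ECDF constrains a continuous minorant by its left limits);
# deviations are measured against the post-jump values i/n.
.gcm_deviation <- function(x, m, n) {
  lower <- (seq_len(m) - 1) / n
  upper <- seq_len(m) / n
  if (m == 1L) return(upper[1L] - lower[1L])
  hull <- integer(m)
  h <- 0L
  for (i in seq_len(m)) {
    while (h >= 2L) {
      a <- hull[h - 1L]; b <- hull[h]
      # pop b if it lies on or above segment a--i
      cross <- (x[b] - x[a]) * (lower[i] - lower[a]) -
        (lower[b] - lower[a]) * (x[i] - x[a])
      if (cross <= 0) h <- h - 1L else break
    }
    h <- h + 1L
    hull[h] <- i
  }
  hull <- hull[seq_len(h)]
  hv <- stats::approx(x[hull], lower[hull], xout = x[seq_len(m)],
                      ties = min, rule = 2)$y
  max(upper[seq_len(m)] - hv)
}

# Symmetric: max deviation of the LCM above the ECDF on the suffix m..n,
# by reflecting the sample.
.lcm_deviation <- function(x, m, n) {
  xr <- -rev(x)
  .gcm_deviation(xr, n - m + 1L, n)
}

#' Dip statistic for unimodality
#'
#' @param values numeric vector (>= 10 observations for the test; the bare
#'   statistic is computed for any n >= 2).
#' @return the dip statistic (0 for constant input).
#' @seealso [dip_unimodality_test()]
#' @export
dip_statistic <- function(values) {
  x <- sort(values[!is.na(values)])
  n <- length(x)
  if (n < 2L || x[n] == x[1L]) return(0)
  el <- function(m) .gcm_deviation(x, m, n)
  er <- function(m) .lcm_deviation(x, m, n)
  lo <- 1L
  hi <- n
  while (hi - lo > 2L) {
    mid <- (lo + hi) %/% 2L
    if (el(mid) < er(mid)) lo <- mid else hi <- mid
  }
  cand <- unique(pmax(1L, pmin(n, seq(lo - 1L, hi + 1L))))
  min(vapply(cand, function(m) max(el(m), er(m)), numeric(1))) / 2
}

#' Bootstrap-calibrated dip test for unimodality
#'
#' Computes [dip_statistic()] for the data and calibrates its p value
#' against `n_boot` uniform samples of the same size (uniform data are the
#' classical least-favourable unimodal null). Small p values indicate
#' departure from unimodality (e.g. a mixture of two well-separated
#' components).
#'
#' @param values numeric vector, at least 10 observations.
#' @param n_boot number of bootstrap samples (>= 100).
#' @param seed optional RNG seed.
#' @return a list with `statistic` and `p_value`; a constant vector gives
#'   `statistic = 0`, `p_value = 1`.
#' @export
dip_unimodality_test <- function(values, n_boot = 500L, seed = NULL) {
  values <- values[!is.na(values)]
  if (length(values) < 10L) stop("need at least 10 values", call. = FALSE)
  if (n_boot < 100L) stop("need n_boot >= 100", call. = FALSE)
  d <- dip_statistic(values)
  if (d == 0) return(list(statistic = 0, p_value = 1))
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  boots <- vapply(seq_len(n_boot), function(i) dip_statistic(stats::runif(n)),
                  numeric(1))
  list(statistic = d,
       p_value = (1 + sum(boots >= d)) / (1 + n_boot))
}
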