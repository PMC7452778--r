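# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately avoid the code paths they check.

# two-sided Fisher p by explicit enumeration of all tables with the
# observed margins, point probabilities via log-factorials
oracle_fisher <- function(ga, gb, ta, tb) {
  r1 <- ga + gb
  r2 <- ta + tb
  k <- ga + ta
  support <- max(0L, k - r2):min(k, r1)
  lp <- lchoose(r1, support) + lchoose(r2, k - support) -
    lchoose(r1 + r2, k)
  probs <- exp(lp)
  pobs <- probs[support == ga]
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# Benjamini-Hochberg step-up by its definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q_sorted[i] <- min(1, min(p[o][js] * m / js))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# upper-tail hypergeometric P(X >= q) by summing binomial coefficients
oracle_hyper_upper <- function(q, m, n, k) {
  js <- q:min(m, k)
  js <- js[js >= max(0, k - n)]
  if (!length(js)) return(0)
  sum(choose(m, js) * choose(n, k - js)) / choose(m + n, k)
}

# all permutations of 1..n (recursive; for tiny n only)
oracle_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in oracle_permutations(n - 1L)) {
      out[[length(out) + 1L]] <- c(i, seq_len(n)[-i][p])
    }
  }
  out
}

# DBSCAN ground truth via density reachability on brute-force pairwise
# distances: core points are connected into components; border points
# attach to any reachable component; everything else is noise. Returns a
# list of clusters as locus-index sets (unordered).
oracle_density_clusters <- function(X, eps, min_pts) {
  n <- nrow(X)
  d <- as.matrix(dist(X))
  nbr <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nbr, length, integer(1)) >= min_pts
  comp <- rep(NA_integer_, n)
  cl <- 0L
  for (i in which(core)) {
    if (!is.na(comp[i])) next
    cl <- cl + 1L
    frontier <- i
    while (length(frontier)) {
      comp[frontier] <- cl
      nxt <- unique(unlist(nbr[frontier]))
      frontier <- nxt[core[nxt] & is.na(comp[nxt])]
    }
  }
  # border points: reachable from some core point
  for (i in which(!core)) {
    cores_near <- nbr[[i]][core[nbr[[i]]]]
    if (length(cores_near)) comp[i] <- comp[cores_near[1L]]
  }
  split(seq_len(n), comp)
}

# build a one-or-more-population count table from per-population count
# matrices given as a list of 4-column (ga, gb, ta, tb) matrices
make_table <- function(..., locus_ids = NULL) {
  popmats <- list(...)
  n <- nrow(popmats[[1L]])
  if (is.null(locus_ids)) locus_ids <- paste0("L", seq_len(n))
  pops <- paste0("P", seq_along(popmats))
  grab <- function(k) {
    m <- vapply(popmats, function(pm) as.integer(pm[, k]), integer(n))
    if (is.null(dim(m))) m <- matrix(m, nrow = n)
    dimnames(m) <- list(locus_ids, pops)
    m
  }
  count_table(grab(1L), grab(2L), grab(3L), grab(4L))
}

# study-condition null-model parameters and the proportional shape-on-mean
# regression used throughout the suite
study_noise_params <- function() noise_params(30, 8, 0.4, 0.4, 2, 0.1)
study_theta_reg <- function() {
  mu <- c(20, 25, 30, 35, 40)
  fit_theta_mu(mu, mu * 8 / 30)
}
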