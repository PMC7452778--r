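# Allele-frequency statistics for pooled samples: B-allele frequency (BAF)
# and B-allele relative expression (BARE), the moment-form fixation index
# F_ST = var(p) / (pbar (1 - pbar)), the Lewontin-Krakauer statistic
# LK = (n - 1) F_ST / mean(F_ST) (chi-squared with n - 1 df under
# neutrality), pairwise F_ST matrices, and a permutation Mantel test for
# isolation-by-distance.

#' Allele fraction
#'
#' `count_x / (count_x + count_y)`; `NA` when both counts are zero
#' (the fraction is undefined without coverage). Vectorised.
#'
#' @param count_x,count_y non-negative integer read counts.
#' @return numeric vector in [0, 1], `NA` where undefined.
#' @export
allele_fraction <- function(count_x, count_y) {
  if (any(count_x < 0, na.rm = TRUE) || any(count_y < 0, na.rm = TRUE)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  tot <- count_x + count_y
  out <- ifelse(tot > 0, count_x / tot, NA_real_)
  as.numeric(out)
}

#' BAF and BARE matrices
#'
#' BAF = G_B / (G_A + G_B) and BARE = T_B / (T_A + T_B) per locus and
#' population; `NA` where the denominator is zero.
#'
#' @param x a [count_table()].
#' @return a list with numeric matrices `baf` and `bare`
#'   (loci x populations).
#' @export
freq_matrix <- function(x) {
  stopifnot(inherits(x, "count_table"))
  gd <- genomic_depth(x)
  el <- expression_level(x)
  baf <- ifelse(gd > 0, x$gb / gd, NA_real_)
  bare <- ifelse(el > 0, x$tb / el, NA_real_)
  dim(baf) <- dim(bare) <- dim(gd)
  dimnames(baf) <- dimnames(bare) <- dimnames(gd)
  list(baf = baf, bare = bare)
}

#' Global F_ST of one locus
#'
#' Moment estimator `var(p) / (pbar (1 - pbar))` over population allele
#' frequencies, with the population variance (denominator N) so that a
#' fixed difference between two populations gives F_ST = 1. `NA` entries
#' are dropped; monomorphic loci (`pbar` 0 or 1) return `NA` (the statistic
#' is undefined), and zero variance returns 0.
#'
#' @param freqs numeric vector of per-population allele frequencies in
#'   [0, 1] (at least two defined).
#' @return F_ST in [0, 1], or `NA` for monomorphic input.
#' @export
global_fst <- function(freqs) {
  f <- freqs[!is.na(freqs)]
  if (length(f) < 2L) stop("need at least two defined frequencies", call. = FALSE)
  if (any(f < 0 | f > 1)) stop("frequencies must be in [0, 1]", call. = FALSE)
  pbar <- mean(f)
  v <- mean((f - pbar)^2)
  if (pbar <= 0 || pbar >= 1) return(NA_real_)
  if (v == 0) return(0)
  v / (pbar * (1 - pbar))
}

#' Per-locus global F_ST over a frequency matrix
#'
#' Vectorised row-wise version of [global_fst()]: rows with fewer than two
#' defined frequencies or monomorphic means give `NA`.
#'
#' @param freqs numeric matrix (loci x populations) of allele frequencies.
#' @return numeric vector of per-locus F_ST, named by locus.
#' @export
fst_per_locus <- function(freqs) {
  stopifnot(is.matrix(freqs))
  ndef <- rowSums(!is.na(freqs))
  pbar <- rowMeans(freqs, na.rm = TRUE)
  v <- rowMeans((freqs - pbar)^2, na.rm = TRUE)
  out <- ifelse(pbar <= 0 | pbar >= 1, NA_real_,
                ifelse(v == 0, 0, v / (pbar * (1 - pbar))))
  out[ndef < 2L] <- NA_real_
  names(out) <- rownames(freqs)
  out
}

#' Lewontin-Krakauer statistic
#'
#' `LK_i = (n_pops - 1) * fst_i / mean(fst)`. Under neutral differentiation
#' LK follows a chi-squared distribution with `n_pops - 1` degrees of
#' freedom; by construction `mean(LK) = n_pops - 1` exactly.
#'
#' @param fst numeric vector of per-locus F_ST values (NA allowed; the mean
#'   is taken over defined values).
#' @param n_pops number of populations.
#' @return numeric vector of LK values (NA propagated).
#' @export
lk_statistic <- function(fst, n_pops) {
  .assert_scalar_number(n_pops, "n_pops", 2)
  fbar <- mean(fst, na.rm = TRUE)
  if (!is.finite(fbar) || fbar <= 0) {
    stop("mean F_ST must be positive to form LK", call. = FALSE)
  }
  (n_pops - 1) * fst / fbar
}

#' Median pairwise F_ST matrix
#'
#' For every unordered pair of populations, the per-locus two-population
#' F_ST (via the same moment formula) is computed over loci where both
#' frequencies are defined and the pair mean is polymorphic; the median is
#' retained. Diagonal is zero.
#'
#' @param freqs numeric matrix (loci x populations) of allele frequencies.
#' @return symmetric numeric matrix (populations x populations); `NA` for
#'   pairs with no jointly-defined polymorphic locus.
#' @export
pairwise_fst <- function(freqs) {
  stopifnot(is.matrix(freqs))
  k <- ncol(freqs)
  if (k < 2L) stop("need at least two populations", call. = FALSE)
  out <- matrix(0, k, k, dimnames = list(colnames(freqs), colnames(freqs)))
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      f1 <- freqs[, i]
      f2 <- freqs[, j]
      ok <- !is.na(f1) & !is.na(f2)
      pbar <- (f1[ok] + f2[ok]) / 2
      v <- ((f1[ok] - f2[ok])^2) / 4
      fst <- ifelse(pbar <= 0 | pbar >= 1, NA_real_,
                    ifelse(v == 0, 0, v / (pbar * (1 - pbar))))
      med <- stats::median(fst, na.rm = TRUE)
      out[i, j] <- out[j, i] <- if (is.na(med)) NA_real_ else med
    }
  }
  out
}

#' Per-locus F_ST, LK and pairwise summary
#'
#' @param x a [count_table()] (frequencies are BAF).
#' @return a list of class `fst_summary` with `fst` (per-locus global
#'   F_ST), `lk`, `mean_fst`, `n_pops` and `pairwise` (median pairwise
#'   F_ST matrix).
#' @export
fst_summary <- function(x) {
  stopifnot(inherits(x, "count_table"))
  baf <- freq_matrix(x)$baf
  fst <- fst_per_locus(baf)
  n_pops <- length(x$population_ids)
  list_out <- list(fst = fst,
                   lk = lk_statistic(fst, n_pops),
                   mean_fst = mean(fst, na.rm = TRUE),
                   n_pops = n_pops,
                   pairwise = pairwise_fst(baf))
  structure(list_out, class = "fst_summary")
}

#' Great-circle distance matrix from population coordinates
#'
#' @param meta data.frame as returned by [read_population_meta()].
#' @param method `"greatcircle"` (geodesic, km; the default) or
#'   `"euclidean"` (planar on decimal degrees).
#' @return symmetric distance matrix (populations x populations).
#' @export
geo_distance_matrix <- function(meta, method = c("greatcircle", "euclidean")) {
  method <- match.arg(method)
  stopifnot(all(c("population_id", "latitude", "longitude") %in% names(meta)))
  n <- nrow(meta)
  out <- matrix(0, n, n, dimnames = list(meta$population_id, meta$population_id))
  pts <- cbind(meta$longitude, meta$latitude)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        d <- if (method == "greatcircle") {
          geosphere::distGeo(pts[i, ], pts[j, ]) / 1000
        } else {
          sqrt(sum((pts[i, ] - pts[j, ])^2))
        }
        out[i, j] <- out[j, i] <- d
      }
    }
  }
  out
}

.all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in .all_permutations(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Mantel test
#'
#' Pearson correlation between the upper triangles of two distance
#' matrices, with significance by joint row/column permutation of `d2`.
#' When `factorial(n) <= n_perm` all permutations are enumerated and the p
#' value is the exact fraction of permutations (including the identity)
#' with `r >= r_observed`; otherwise `n_perm` random permutations are drawn
#' and the observed statistic is included in numerator and denominator.
#'
#' @param d1,d2 square symmetric matrices of matching dimension (>= 3).
#' @param n_perm number of permutations.
#' @param seed optional RNG seed.
#' @return a list with `r` (NA when `d2` has zero variance, in which case
#'   `p` is 1), `p`, and `n_perm_used`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999L, seed = NULL) {
  d1 <- as.matrix(d1)
  d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2)) || nrow(d1) != ncol(d1)) {
    stop("d1 and d2 must be square matrices of matching dimension", call. = FALSE)
  }
  n <- nrow(d1)
  if (n < 3L) stop("need at least 3 populations", call. = FALSE)
  ut <- upper.tri(d1)
  v1 <- d1[ut]
  rfun <- function(m) {
    v2 <- m[ut]
    if (stats::sd(v1) == 0 || stats::sd(v2) == 0) return(NA_real_)
    stats::cor(v1, v2)
  }
  r_obs <- rfun(d2)
  if (is.na(r_obs)) {
    return(list(r = NA_real_, p = 1, n_perm_used = 0L))
  }
  if (!is.null(seed)) set.seed(seed)
  if (factorial(n) <= n_perm) {
    perms <- .all_permutations(n)
    rs <- vapply(perms, function(p) rfun(d2[p, p]), numeric(1))
    p <- mean(rs >= r_obs - 1e-12)
    n_used <- length(perms)
  } else {
    rs <- vapply(seq_len(n_perm), function(k) {
      p <- sample.int(n)
      rfun(d2[p, p])
    }, numeric(1))
    p <- (1 + sum(rs >= r_obs - 1e-12, na.rm = TRUE)) / (1 + n_perm)
    n_used <- n_perm
  }
  list(r = r_obs, p = p, n_perm_used = n_used)
}
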