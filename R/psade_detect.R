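# The psADE detector: in each population independently, compare the
# genomic allele balance (G_A, G_B) with the transcriptomic allele balance
# (T_A, T_B) of every eligible locus by a two-sided Fisher exact test,
# control the FDR by Benjamini-Hochberg across that population's tested
# loci, and report calls with q below the FDR threshold together with the
# descriptive statistic D = BAF - BARE.

# Two-sided (point-probability / "minlike") Fisher p for a single 2x2
# table with rows (ga, gb) and (ta, tb): sum of hypergeometric point
# probabilities not exceeding that of the observed table, with a 1e-7
# relative tolerance for ties (the convention of mainstream
# implementations).
.fisher_p <- function(ga, gb, ta, tb) {
  m <- ga + gb          # genomic reads
  n <- ta + tb          # transcriptomic reads
  k <- ga + ta          # reads supporting allele A
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  d <- stats::dhyper(support, m, n, k)
  dobs <- stats::dhyper(ga, m, n, k)
  min(1, sum(d[d <= dobs * (1 + 1e-7)]))
}

#' Two-sided Fisher exact test on a 2x2 allele-count table
#'
#' Exact two-sided p value for independence of allele support between the
#' genomic row (`g_a`, `g_b`) and transcriptomic row (`t_a`, `t_b`),
#' defined as the sum of hypergeometric probabilities of all tables with
#' the same margins whose point probability does not exceed the observed
#' one (relative tie tolerance 1e-7).
#'
#' @param g_a,g_b,t_a,t_b non-negative integer read counts; both row sums
#'   must be positive.
#' @return p value in (0, 1].
#' @examples
#' fisher_exact_2x2(5, 5, 5, 5)   # 1
#' fisher_exact_2x2(10, 0, 0, 10) # 2 / choose(20, 10)
#' @export
fisher_exact_2x2 <- function(g_a, g_b, t_a, t_b) {
  counts <- c(g_a, g_b, t_a, t_b)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (g_a + g_b == 0 || t_a + t_b == 0) {
    stop("not testable: a zero row sum (no genomic or no transcriptomic reads)",
         call. = FALSE)
  }
  .fisher_p(g_a, g_b, t_a, t_b)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} (p_(j) * m / j)` capped at 1 and mapped back to
#' input order; monotone in p and invariant under permutation of the
#' input.
#'
#' @param pvals numeric vector of p values in [0, 1].
#' @return q values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric())
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Detect population-scale allelic differential expression
#'
#' Per population independently: eligible loci are heterozygous in the
#' population sense (defined BAF strictly inside (0, 1)) with non-null
#' expression (`T_A + T_B > 0`). Each eligible locus is tested with
#' [fisher_exact_2x2()]; q values are Benjamini-Hochberg adjusted across
#' that population's eligible loci only, and loci with `q < fdr` are
#' called. `D = BAF - BARE` and the favoured allele (the one whose
#' relative expression exceeds its genomic frequency) are attached.
#'
#' @param x a [count_table()].
#' @param fdr FDR threshold in (0, 1).
#' @return a data.frame of class `psade_calls` with one row per tested
#'   (locus, population) pair and columns `locus_id`, `population_id`,
#'   `ga`, `gb`, `ta`, `tb`, `baf`, `bare`, `d`, `p`, `q`,
#'   `favored_allele`, `called`; the per-population number of tested loci
#'   is in `attr(, "tested")`.
#' @export
detect_psade <- function(x, fdr = 0.05) {
  stopifnot(inherits(x, "count_table"))
  .assert_scalar_number(fdr, "fdr", 0, 1)
  fm <- freq_matrix(x)
  el <- expression_level(x)
  res <- vector("list", length(x$population_ids))
  tested <- integer(length(x$population_ids))
  names(tested) <- x$population_ids
  for (j in seq_along(x$population_ids)) {
    baf <- fm$baf[, j]
    eligible <- which(!is.na(baf) & baf > 0 & baf < 1 & el[, j] > 0L)
    tested[j] <- length(eligible)
    if (!length(eligible)) next
    ga <- x$ga[eligible, j]; gb <- x$gb[eligible, j]
    ta <- x$ta[eligible, j]; tb <- x$tb[eligible, j]
    p <- vapply(seq_along(eligible),
                function(i) .fisher_p(ga[i], gb[i], ta[i], tb[i]), numeric(1))
    q <- bh_adjust(p)
    bare <- fm$bare[eligible, j]
    d <- baf[eligible] - bare
    fav <- ifelse(bare > baf[eligible], "B",
                  ifelse(bare < baf[eligible], "A", NA_character_))
    res[[j]] <- data.frame(
      locus_id = x$locus_ids[eligible],
      population_id = x$population_ids[j],
      ga = ga, gb = gb, ta = ta, tb = tb,
      baf = baf[eligible], bare = bare, d = d, p = p, q = q,
      favored_allele = fav, called = q < fdr,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(locus_id = character(), population_id = character(),
                      ga = integer(), gb = integer(), ta = integer(),
                      tb = integer(), baf = numeric(), bare = numeric(),
                      d = numeric(), p = numeric(), q = numeric(),
                      favored_allele = character(), called = logical(),
                      stringsAsFactors = FALSE)
  }
  attr(out, "tested") <- tested
  attr(out, "fdr") <- fdr
  class(out) <- c("psade_calls", class(out))
  out
}

#' Per-population sets of called loci
#'
#' @param calls result of [detect_psade()].
#' @return named list (one element per population with at least one tested
#'   locus) of character vectors of called locus ids; populations with no
#'   calls yield empty vectors.
#' @export
psade_call_sets <- function(calls) {
  stopifnot(inherits(calls, "psade_calls"))
  pops <- names(attr(calls, "tested"))
  out <- lapply(pops, function(p) {
    calls$locus_id[calls$population_id == p & calls$called]
  })
  names(out) <- pops
  out
}

#' Maximum-likelihood Gaussian fit of the D statistic
#'
#' ML normal fit (mean, and standard deviation with denominator N). A
#' constant vector is flagged degenerate with `sigma = 0`.
#'
#' @param d_values numeric vector (>= 2 values).
#' @return a list with `mu`, `sigma`, `degenerate`.
#' @export
fit_d_gaussian <- function(d_values) {
  d <- d_values[!is.na(d_values)]
  if (length(d) < 2L) stop("need at least two values", call. = FALSE)
  mu <- mean(d)
  sigma <- sqrt(mean((d - mu)^2))
  list(mu = mu, sigma = sigma, degenerate = sigma == 0)
}

#' Linear regression of allele relative expression on allele frequency
#'
#' OLS of BARE on BAF over loci where both are defined, plus the Pearson
#' correlation. In well-behaved data the relation is close to the identity
#' line: the more an allele is observed genomically, the more it is
#' expressed.
#'
#' @param baf,bare numeric vectors (paired; NA pairs dropped; >= 3
#'   complete pairs required).
#' @return a list with `slope`, `intercept`, `r` (NA when BARE has zero
#'   variance), `n`.
#' @export
baf_bare_regression <- function(baf, bare) {
  ok <- !is.na(baf) & !is.na(bare)
  baf <- baf[ok]; bare <- bare[ok]
  if (length(baf) < 3L) stop("need at least three complete (BAF, BARE) pairs",
                             call. = FALSE)
  if (stats::sd(baf) == 0) stop("zero variance in BAF", call. = FALSE)
  fit <- stats::lm(bare ~ baf)
  r <- if (stats::sd(bare) == 0) NA_real_ else stats::cor(baf, bare)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r = r, n = length(baf))
}
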