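# How psADE sharing relates to population differentiation: every called
# locus belongs to exactly one "exclusive crossing" (the combination of
# populations that called it, upset-plot style); each crossing gets the
# median F_ST computed over the populations of the set; and the number of
# shared calls is modelled as an exponential decay in differentiation,
# y = a * exp(-b x) + c.

#' Exclusive crossings of per-population call sets
#'
#' Assigns each called locus to the exact combination of populations that
#' called it and counts loci per non-empty combination. The counts
#' partition the called loci: they sum to the number of distinct called
#' loci.
#'
#' @param call_sets named list of character vectors (population ->
#'   called locus ids), e.g. from [psade_call_sets()].
#' @return a data.frame with `population_set` (population ids joined by
#'   `"+"`, in `names(call_sets)` order), `n_pops`, `shared_count`.
#' @export
exclusive_crossings <- function(call_sets) {
  if (!length(call_sets) || is.null(names(call_sets))) {
    stop("call_sets must be a non-empty named list", call. = FALSE)
  }
  pops <- names(call_sets)
  loci <- unique(unlist(call_sets, use.names = FALSE))
  if (!length(loci)) {
    return(data.frame(population_set = character(), n_pops = integer(),
                      shared_count = integer(), stringsAsFactors = FALSE))
  }
  member <- vapply(pops, function(p) loci %in% call_sets[[p]],
                   logical(length(loci)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1L)
  key <- apply(member, 1L, function(row) paste(pops[row], collapse = "+"))
  counts <- table(key)
  data.frame(population_set = names(counts),
             n_pops = lengths(strsplit(names(counts), "+", fixed = TRUE)),
             shared_count = as.integer(counts),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Median F_ST of a population set
#'
#' Per-locus global F_ST over the populations in the set, median over loci
#' with defined values. Singleton sets are 0 by convention (the natural
#' limit: no differentiation is measurable within one population), so
#' population-specific crossings sit at the origin of the decay model.
#'
#' @param freqs numeric matrix (loci x populations) of allele frequencies
#'   (e.g. BAF).
#' @param population_set character vector of population ids (columns of
#'   `freqs`).
#' @return median F_ST (scalar).
#' @export
median_fst_for_set <- function(freqs, population_set) {
  stopifnot(is.matrix(freqs))
  if (!all(population_set %in% colnames(freqs))) {
    stop("unknown population(s): ",
         paste(setdiff(population_set, colnames(freqs)), collapse = ", "),
         call. = FALSE)
  }
  if (length(population_set) < 2L) return(0)
  fst <- fst_per_locus(freqs[, population_set, drop = FALSE])
  med <- stats::median(fst, na.rm = TRUE)
  if (is.na(med)) stop("no locus with defined F_ST for this set", call. = FALSE)
  med
}

#' Crossing records with differentiation
#'
#' Convenience: [exclusive_crossings()] plus the [median_fst_for_set()]
#' of every combination.
#'
#' @inheritParams exclusive_crossings
#' @inheritParams median_fst_for_set
#' @return the crossings data.frame with an extra `median_fst` column.
#' @export
crossing_records <- function(call_sets, freqs) {
  cr <- exclusive_crossings(call_sets)
  cr$median_fst <- vapply(strsplit(cr$population_set, "+", fixed = TRUE),
                          function(s) median_fst_for_set(freqs, s), numeric(1))
  cr
}

#' Fit an exponential decay y = a exp(-b x) + c
#'
#' Starting values come from the linearisation `log(y - c0) ~ x` with
#' `c0 = 0.5 * min(y)` (points where `y - c0 <= 0` are excluded from the
#' linearisation only); since the model carries `exp(-b x)`, the decay
#' rate starts at minus the linear slope. The nonlinear fit is
#' Levenberg-Marquardt least squares.
#'
#' @param x,y numeric vectors (>= 4 points; `y > 0`).
#' @param exclude_singletons optionally drop points with `x == 0` before
#'   fitting (population-specific crossings).
#' @return a list of class `exp_decay_fit`: `a`, `b`, `c`, `fitted`,
#'   `pearson_r` (fitted vs observed), `p` (two-sided), `converged`,
#'   `start`.
#' @export
fit_exp_decay <- function(x, y, exclude_singletons = FALSE) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (exclude_singletons) {
    keep <- x != 0
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 4L) stop("need at least 4 points", call. = FALSE)
  if (any(y <= 0)) stop("all y must be positive", call. = FALSE)
  if (stats::sd(y) == 0) {
    return(structure(list(a = 0, b = 0, c = y[[1L]], fitted = y,
                          pearson_r = NA_real_, p = NA_real_,
                          converged = TRUE, degenerate = TRUE,
                          start = c(a = 0, b = 0, c = y[[1L]])),
                     class = "exp_decay_fit"))
  }
  c0 <- 0.5 * min(y)
  ok <- (y - c0) > 0
  if (sum(ok) < 3L) stop("too few points usable for linearised start", call. = FALSE)
  lin <- stats::lm(log(y[ok] - c0) ~ x[ok])
  a0 <- exp(unname(stats::coef(lin)[1L]))
  b0 <- -unname(stats::coef(lin)[2L])
  start <- c(a = a0, b = b0, c = c0)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-b * x) + c,
                      start = as.list(start),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    stop("nonlinear fit did not converge (start: a=", signif(a0, 4),
         ", b=", signif(b0, 4), ", c=", signif(c0, 4), ")", call. = FALSE)
  }
  cf <- stats::coef(fit)
  fitted <- as.numeric(stats::fitted(fit))
  ct <- if (stats::sd(fitted) == 0) NULL else stats::cor.test(fitted, y)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
                 fitted = fitted,
                 pearson_r = if (is.null(ct)) NA_real_ else unname(ct$estimate),
                 p = if (is.null(ct)) NA_real_ else ct$p.value,
                 converged = TRUE, degenerate = FALSE, start = start),
            class = "exp_decay_fit")
}
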