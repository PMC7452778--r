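# Synthetic count tables with known ground truth. Population structure
# follows the Balding-Nichols model: an ancestral allele frequency is
# drawn from a (typically U-shaped) beta law, and each population's
# frequency from Beta(p(1-F)/F, (1-p)(1-F)/F), which has mean p and
# variance F p (1-p) -- F is a direct F_ST dial. Optional population
# groups add hierarchy (a shared intermediate draw at `fst_target`, then
# within-group draws at `within_fst`), giving genetically close and
# distant population pairs like real oceanographic samples. Counts reuse
# the null simulator's laws (NB genomic coverage with shape proportional
# to mean, gamma expression, Poisson transcriptomic counts). psADE is
# planted by displacing the transcriptomic allele frequency of affected
# (locus, population) pairs by a fixed shift; "selected" loci get one
# population's genomic frequency displaced toward fixation.

#' Synthetic-data configuration
#'
#' Defaults mirror a seven-population pooled metagenomic/metatranscriptomic
#' survey of one abundant species: moderate differentiation (F_ST 0.1), a
#' U-shaped ancestral frequency spectrum (Beta(0.4, 0.4)), genomic
#' coverage NB(mean 30, shape 8), expression level Gamma(shape 2, rate
#' 0.1) (mean 20), about 2% of loci under psADE with a transcriptomic
#' frequency shift of 0.4, and about 2.6% of loci under selection.
#'
#' @param n_pops number of populations.
#' @param n_loci number of loci.
#' @param fst_target Balding-Nichols F (between-group differentiation
#'   when `pop_groups` is set).
#' @param ancestral_alpha,ancestral_beta beta shapes of the ancestral
#'   frequency spectrum.
#' @param coverage_mu,coverage_theta NB mean and shape of genomic depth;
#'   the allele-level shape scales proportionally with the allele mean
#'   (`theta(mu') = coverage_theta * mu' / coverage_mu`).
#' @param expr_shape,expr_rate gamma law of the expression level.
#' @param psade_fraction fraction of loci with a planted psADE effect.
#' @param psade_shift displacement of the transcriptomic allele frequency
#'   in affected populations, in (0, 1].
#' @param selected_fraction fraction of loci planted as "under selection".
#' @param pop_groups optional integer vector (length `n_pops`) of group
#'   memberships; populations of one group share an intermediate ancestral
#'   draw and differ only by `within_fst`.
#' @param within_fst within-group Balding-Nichols F.
#' @param transcript_coupling how the transcriptomic allele frequency of a
#'   non-psADE locus relates to the genome: `"realized"` (default) couples
#'   it to the realised genomic allele fraction of the pool, making such
#'   loci exactly null for the detector; `"latent"` couples it to the
#'   latent population frequency, so genomic and transcriptomic counts are
#'   two independent noisy readings of it -- the decoupling-noise regime
#'   the null simulator models.
#' @param seed root RNG seed; child seeds for frequencies, counts and
#'   effect placement are derived deterministically.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_pops = 7L, n_loci = 5000L, fst_target = 0.1,
                         ancestral_alpha = 0.4, ancestral_beta = 0.4,
                         coverage_mu = 30, coverage_theta = 8,
                         expr_shape = 2, expr_rate = 0.1,
                         psade_fraction = 0.02, psade_shift = 0.4,
                         selected_fraction = 0.026,
                         pop_groups = NULL, within_fst = 0.02,
                         transcript_coupling = c("realized", "latent"),
                         seed = 1L) {
  transcript_coupling <- match.arg(transcript_coupling)
  .assert_scalar_number(n_pops, "n_pops", 1)
  .assert_scalar_number(n_loci, "n_loci", 1)
  .assert_scalar_number(fst_target, "fst_target")
  if (fst_target <= 0 || fst_target >= 1) stop("fst_target must be in (0, 1)",
                                               call. = FALSE)
  for (nm in c("ancestral_alpha", "ancestral_beta", "coverage_mu",
               "coverage_theta", "expr_shape", "expr_rate")) {
    if (get(nm) <= 0) stop("'", nm, "' must be positive", call. = FALSE)
  }
  .assert_scalar_number(psade_fraction, "psade_fraction", 0, 1)
  .assert_scalar_number(psade_shift, "psade_shift", 0, 1)
  .assert_scalar_number(selected_fraction, "selected_fraction", 0, 1)
  if (!is.null(pop_groups)) {
    stopifnot(length(pop_groups) == n_pops)
    .assert_scalar_number(within_fst, "within_fst")
    if (within_fst <= 0 || within_fst >= 1) {
      stop("within_fst must be in (0, 1)", call. = FALSE)
    }
  }
  structure(list(n_pops = as.integer(n_pops), n_loci = as.integer(n_loci),
                 fst_target = fst_target, ancestral_alpha = ancestral_alpha,
                 ancestral_beta = ancestral_beta, coverage_mu = coverage_mu,
                 coverage_theta = coverage_theta, expr_shape = expr_shape,
                 expr_rate = expr_rate, psade_fraction = psade_fraction,
                 psade_shift = psade_shift,
                 selected_fraction = selected_fraction,
                 pop_groups = pop_groups, within_fst = within_fst,
                 transcript_coupling = transcript_coupling,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# one Balding-Nichols draw per element of p at differentiation F;
# degenerate ancestral frequencies (0 or 1) stay fixed
.bn_draw <- function(p, F) {
  out <- p
  interior <- p > 0 & p < 1
  if (any(interior)) {
    s <- (1 - F) / F
    out[interior] <- stats::rbeta(sum(interior), p[interior] * s,
                                  (1 - p[interior]) * s)
  }
  out
}

#' Generate structured true allele frequencies
#'
#' Ancestral frequency `p ~ Beta(ancestral_alpha, ancestral_beta)` per
#' locus, then per-population Balding-Nichols draws (hierarchically through
#' `pop_groups` when set). Loci planted as "selected" get one random
#' population's frequency displaced 80% of the way toward the nearest
#' fixation boundary, so their per-locus F_ST stochastically dominates
#' neutral loci.
#'
#' @param cfg a [synth_config()].
#' @return a list with `freqs` (loci x populations matrix of true A-allele
#'   frequencies), `ancestral`, `is_selected` (logical per locus),
#'   `selected_pop` (population index carrying the displacement, NA
#'   otherwise).
#' @export
generate_structured_freqs <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(derive_seed(cfg$seed, 1L))
  n <- cfg$n_loci
  k <- cfg$n_pops
  p0 <- stats::rbeta(n, cfg$ancestral_alpha, cfg$ancestral_beta)
  freqs <- matrix(NA_real_, n, k,
                  dimnames = list(sprintf("S%06d", seq_len(n)),
                                  sprintf("POP%d", seq_len(k))))
  if (is.null(cfg$pop_groups)) {
    for (j in seq_len(k)) freqs[, j] <- .bn_draw(p0, cfg$fst_target)
  } else {
    groups <- unique(cfg$pop_groups)
    for (g in groups) {
      pg <- .bn_draw(p0, cfg$fst_target)
      for (j in which(cfg$pop_groups == g)) {
        freqs[, j] <- .bn_draw(pg, cfg$within_fst)
      }
    }
  }
  n_sel <- round(cfg$selected_fraction * n)
  is_selected <- rep(FALSE, n)
  selected_pop <- rep(NA_integer_, n)
  if (n_sel > 0) {
    sel <- sample.int(n, n_sel)
    is_selected[sel] <- TRUE
    selected_pop[sel] <- sample.int(k, n_sel, replace = TRUE)
    for (i in sel) {
      j <- selected_pop[i]
      f <- freqs[i, j]
      target <- if (f >= 0.5) 1 else 0
      freqs[i, j] <- f + 0.8 * (target - f)
    }
  }
  list(freqs = freqs, ancestral = p0, is_selected = is_selected,
       selected_pop = selected_pop)
}

#' Generate a synthetic count table with ground truth
#'
#' Genomic counts follow the null simulator's recipe at each population's
#' true frequency (NB at allele-level means, shape proportional to mean);
#' transcriptomic counts are Poisson around the expression level split by
#' the *transcriptomic* allele frequency. For non-psADE loci that
#' frequency equals the realised genomic allele frequency of the pool
#' (`G_A / (G_A + G_B)`; the same individuals are sequenced at both
#' levels, so expression mirrors the allelic composition actually
#' sampled -- and such loci are exactly null for the detector). At
#' planted psADE (locus, population) pairs it is
#' `clamp(freq +/- psade_shift, 0, 1)` (one random sign per locus).
#' Effects are planted in every population whose true frequency lies in
#' [0.1, 0.9] -- a locus must be detectably heterozygous for allelic
#' expression imbalance to be observable, and frequency-dependent
#' placement makes genetically similar populations share planted effects.
#'
#' @param cfg a [synth_config()].
#' @return a list with `table` (a [count_table()]) and `truth`: `freqs`,
#'   `is_psade` (loci x populations logical), `psade_sign`, `is_selected`,
#'   `selected_pop`.
#' @export
generate_table <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  sf <- generate_structured_freqs(cfg)
  n <- cfg$n_loci
  k <- cfg$n_pops
  set.seed(derive_seed(cfg$seed, 2L))
  n_ade <- round(cfg$psade_fraction * n)
  is_psade <- matrix(FALSE, n, k, dimnames = dimnames(sf$freqs))
  psade_sign <- rep(NA_integer_, n)
  if (n_ade > 0 && cfg$psade_shift > 0) {
    ade <- sample.int(n, n_ade)
    psade_sign[ade] <- sample(c(-1L, 1L), n_ade, replace = TRUE)
    band <- sf$freqs >= 0.1 & sf$freqs <= 0.9
    is_psade[ade, ] <- band[ade, , drop = FALSE]
  }
  reg <- structure(list(slope = cfg$coverage_theta / cfg$coverage_mu,
                        intercept = 0, theta_floor = 0.01),
                   class = "theta_mu_regression")
  ga <- gb <- ta <- tb <- matrix(0L, n, k, dimnames = dimnames(sf$freqs))
  for (j in seq_len(k)) {
    f <- sf$freqs[, j]
    ga_bar <- f * cfg$coverage_mu
    gb_bar <- cfg$coverage_mu - ga_bar
    ga[, j] <- stats::rnbinom(n, mu = ga_bar, size = predict_theta(reg, ga_bar))
    gb[, j] <- stats::rnbinom(n, mu = gb_bar, size = predict_theta(reg, gb_bar))
    e <- stats::rgamma(n, shape = cfg$expr_shape, rate = cfg$expr_rate)
    if (cfg$transcript_coupling == "latent") {
      tf <- f
    } else {
      dep <- ga[, j] + gb[, j]
      tf <- ifelse(dep > 0L, ga[, j] / dep, f)
    }
    aff <- which(is_psade[, j])
    if (length(aff)) {
      tf[aff] <- pmin(1, pmax(0, tf[aff] + psade_sign[aff] * cfg$psade_shift))
    }
    ta[, j] <- stats::rpois(n, tf * e)
    tb[, j] <- stats::rpois(n, (1 - tf) * e)
  }
  tab <- count_table(ga, gb, ta, tb)
  list(table = tab,
       truth = list(freqs = sf$freqs, is_psade = is_psade,
                    psade_sign = psade_sign, is_selected = sf$is_selected,
                    selected_pop = sf$selected_pop,
                    ancestral = sf$ancestral))
}

#' Write synthetic truth labels to TSV
#'
#' @param truth the `truth` element of [generate_table()]'s result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_labels <- function(truth, path) {
  df <- data.frame(locus_id = rownames(truth$freqs),
                   is_selected = as.integer(truth$is_selected),
                   selected_pop = truth$selected_pop,
                   psade_sign = truth$psade_sign,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(truth$freqs))) {
    df[[paste0(colnames(truth$freqs)[j], ".freq")]] <- truth$freqs[, j]
    df[[paste0(colnames(truth$freqs)[j], ".psade")]] <-
      as.integer(truth$is_psade[, j])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
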