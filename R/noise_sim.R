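# Generative null model for noise calibration. Per population, four laws
# are learned from the data by maximum likelihood: genomic depth of
# coverage ~ negative binomial (mean mu, shape theta; variance
# mu + mu^2/theta), A-allele frequency ~ beta(alpha, beta) (U-shaped in
# pooled data), expression level ~ gamma(shape a, rate b). A linear
# regression of theta on mu across populations supplies a shape for any
# allele-level mean. Null (psADE-free) loci are then simulated: a beta
# frequency f, expected allele-A genomic count f*mu with NB draws at
# allele-level means, a gamma expression level E, and Poisson
# transcriptomic counts around f*E and (1-f)*E -- so the transcriptomic
# allele balance matches the genomic frequency by construction.

# ML fit of the beta allele-frequency law with the latent frequency
# integrated out: the likelihood of a locus's (G_A, G_B) pair is
# int NB(G_A | f mu, theta f) NB(G_B | (1-f) mu, theta (1-f)) dBeta(f).
# Fitting the beta to *realised* frequencies would attenuate the shape
# parameters (count sampling noise flattens the U), so the integral is
# evaluated on a fixed frequency grid (exact beta interval masses via
# pbeta, so alpha/beta < 1 singularities are handled) and the two shape
# parameters maximised on the log scale. Allele-level NB shapes use the
# proportional link theta(mu') = theta * mu'/mu (constant overdispersion
# coefficient), the same link used by the simulator.
.fit_beta_latent <- function(ga, gb, mu, theta, n_grid = 200L) {
  grid <- seq(0, 1, length.out = n_grid + 1L)
  mid <- (grid[-1L] + grid[-(n_grid + 1L)]) / 2
  slope <- theta / mu
  K <- matrix(0, length(ga), n_grid)
  for (j in seq_len(n_grid)) {
    f <- mid[j]
    K[, j] <- stats::dnbinom(ga, mu = f * mu,
                             size = max(slope * f * mu, 0.01)) *
      stats::dnbinom(gb, mu = (1 - f) * mu,
                     size = max(slope * (1 - f) * mu, 0.01))
  }
  nll <- function(par) {
    w <- diff(stats::pbeta(grid, exp(par[1L]), exp(par[2L])))
    -sum(log(pmax(K %*% w, 1e-300)))
  }
  fit <- stats::optim(c(log(0.5), log(0.5)), nll)
  exp(fit$par)
}

#' Learn per-population generative parameters
#'
#' Maximum-likelihood fits of the three generative laws for one
#' population: a negative binomial (mean `mu`, shape `theta`) on per-locus
#' genomic depth (via [fitdistrplus::fitdist()]); a beta law
#' (`alpha`, `beta`) of the latent A-allele frequency, fitted to the
#' genomic allele counts with the latent frequency integrated out (so
#' count sampling noise does not flatten the U-shaped spectrum); and a
#' gamma law (`gamma_shape a`, `gamma_rate b`) of the latent expression
#' level, recovered through the exact Poisson-gamma identity: expression
#' read totals are then negative binomial with size `a` and mean `a/b`,
#' so an NB fit on the totals is the ML fit of the gamma mixing law.
#'
#' @param x a [count_table()].
#' @param population_id which population to fit.
#' @param min_loci minimum number of loci required.
#' @return a list of class `noise_params`: `mu`, `theta`, `alpha`, `beta`,
#'   `gamma_shape`, `gamma_rate`, `population_id`, `n_loci`.
#' @export
learn_params <- function(x, population_id, min_loci = 50L) {
  stopifnot(inherits(x, "count_table"))
  if (!population_id %in% x$population_ids) {
    stop("unknown population: ", population_id, call. = FALSE)
  }
  depth <- genomic_depth(x)[, population_id]
  if (length(depth) < min_loci) {
    stop("need at least ", min_loci, " loci", call. = FALSE)
  }
  if (stats::sd(depth) == 0) {
    stop("degenerate input for the negative binomial fit: constant depth",
         call. = FALSE)
  }
  nb <- tryCatch(
    fitdistrplus::fitdist(as.numeric(depth), "nbinom"),
    error = function(e) stop("negative binomial fit failed: ",
                             conditionMessage(e), call. = FALSE))
  mu <- unname(nb$estimate["mu"])
  theta <- unname(nb$estimate["size"])
  covered <- depth > 0L
  if (sum(covered) < 10L) {
    stop("degenerate input for the beta fit: too few covered loci",
         call. = FALSE)
  }
  ab <- tryCatch(
    .fit_beta_latent(x$ga[covered, population_id],
                     x$gb[covered, population_id], mu, theta),
    error = function(e) stop("beta fit failed: ", conditionMessage(e),
                             call. = FALSE))
  expr <- as.numeric(expression_level(x)[, population_id])
  if (stats::sd(expr) == 0 || sum(expr > 0) < 10L) {
    stop("degenerate input for the gamma fit: expression levels",
         call. = FALSE)
  }
  ge <- tryCatch(
    fitdistrplus::fitdist(expr, "nbinom"),
    error = function(e) stop("gamma fit failed: ", conditionMessage(e),
                             call. = FALSE))
  gamma_shape <- unname(ge$estimate["size"])
  gamma_rate <- gamma_shape / unname(ge$estimate["mu"])
  structure(list(
    mu = mu,
    theta = theta,
    alpha = ab[1L],
    beta = ab[2L],
    gamma_shape = gamma_shape,
    gamma_rate = gamma_rate,
    population_id = population_id,
    n_loci = length(depth)), class = "noise_params")
}

#' Construct noise parameters directly
#'
#' @param mu,theta negative-binomial mean and shape of genomic depth.
#' @param alpha,beta beta shapes of the A-allele frequency.
#' @param gamma_shape,gamma_rate gamma law of the expression level.
#' @param population_id optional label.
#' @return a `noise_params` object.
#' @export
noise_params <- function(mu, theta, alpha, beta, gamma_shape, gamma_rate,
                         population_id = "SIM") {
  for (nm in c("mu", "theta", "alpha", "beta", "gamma_shape", "gamma_rate")) {
    .assert_scalar_number(get(nm), nm)
    if (get(nm) <= 0) stop("'", nm, "' must be positive", call. = FALSE)
  }
  structure(list(mu = mu, theta = theta, alpha = alpha, beta = beta,
                 gamma_shape = gamma_shape, gamma_rate = gamma_rate,
                 population_id = population_id, n_loci = NA_integer_),
            class = "noise_params")
}

#' Regression of NB shape on NB mean across populations
#'
#' OLS of theta on mu over the per-population fits; predictions are
#' clamped from below at `theta_floor` so simulated shapes stay positive.
#'
#' @param mu,theta numeric vectors of per-population NB means and shapes
#'   (>= 2 populations, distinct mu values).
#' @param theta_floor minimum predicted shape.
#' @return a list of class `theta_mu_regression` with `slope`,
#'   `intercept`, `theta_floor`.
#' @export
fit_theta_mu <- function(mu, theta, theta_floor = 0.01) {
  if (length(mu) < 2L || length(mu) != length(theta)) {
    stop("need matching mu/theta vectors of length >= 2", call. = FALSE)
  }
  if (stats::sd(mu) == 0) stop("identical mu values; cannot regress", call. = FALSE)
  .assert_scalar_number(theta_floor, "theta_floor")
  if (theta_floor <= 0) stop("theta_floor must be positive", call. = FALSE)
  fit <- stats::lm(theta ~ mu)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 theta_floor = theta_floor),
            class = "theta_mu_regression")
}

#' Predict an NB shape for a given mean
#'
#' @param reg a [fit_theta_mu()] regression.
#' @param mu numeric vector of means.
#' @return predicted shapes, clamped at `reg$theta_floor`.
#' @export
predict_theta <- function(reg, mu) {
  stopifnot(inherits(reg, "theta_mu_regression"))
  pmax(reg$slope * mu + reg$intercept, reg$theta_floor)
}

#' Simulate a null (psADE-free) count table for one population
#'
#' Per locus: `f ~ Beta(alpha, beta)`; expected genomic counts
#' `GA = f * mu`, `GB = mu - GA`; realised genomic counts drawn from
#' negative binomials with means `GA`, `GB` and shapes predicted by the
#' theta-on-mu regression at those allele-level means; expression level
#' `E ~ Gamma(a, b)`; expected transcriptomic counts `TA = f * E`,
#' `TB = E - TA` (the *latent* frequency, so genomic and transcriptomic
#' allele balance agree under the null); realised transcriptomic counts
#' Poisson at those means.
#'
#' @param params a `noise_params` object.
#' @param reg a [fit_theta_mu()] regression.
#' @param n_loci number of loci to simulate.
#' @param seed optional RNG seed (fixed seed gives a bit-identical table).
#' @return a one-population [count_table()]; the latent frequencies are in
#'   `attr(, "latent_freq")`.
#' @export
simulate_null <- function(params, reg, n_loci, seed = NULL) {
  stopifnot(inherits(params, "noise_params"),
            inherits(reg, "theta_mu_regression"))
  .assert_scalar_number(n_loci, "n_loci", 1)
  if (!is.null(seed)) set.seed(seed)
  f <- stats::rbeta(n_loci, params$alpha, params$beta)
  ga_bar <- f * params$mu
  gb_bar <- params$mu - ga_bar
  ga <- stats::rnbinom(n_loci, mu = ga_bar, size = predict_theta(reg, ga_bar))
  gb <- stats::rnbinom(n_loci, mu = gb_bar, size = predict_theta(reg, gb_bar))
  e <- stats::rgamma(n_loci, shape = params$gamma_shape, rate = params$gamma_rate)
  ta_bar <- f * e
  tb_bar <- e - ta_bar
  ta <- stats::rpois(n_loci, ta_bar)
  tb <- stats::rpois(n_loci, tb_bar)
  ids <- sprintf("N%06d", seq_len(n_loci))
  mk <- function(v) matrix(as.integer(v), n_loci, 1L,
                           dimnames = list(ids, params$population_id))
  out <- count_table(mk(ga), mk(gb), mk(ta), mk(tb))
  attr(out, "latent_freq") <- f
  out
}

#' Null-model false discovery run
#'
#' Simulates `n_loci` psADE-free loci and runs [detect_psade()] on them;
#' the number of significant loci estimates the noise floor of the
#' detector at the given FDR threshold.
#'
#' @inheritParams simulate_null
#' @param fdr FDR threshold.
#' @return a list of class `null_sim_result`: `tested`, `significant`,
#'   `n_loci`, `fdr`, and the simulated `table`.
#' @export
null_fdr_run <- function(params, reg, n_loci = 50000L, fdr = 0.05,
                         seed = NULL) {
  tab <- simulate_null(params, reg, n_loci, seed)
  calls <- detect_psade(tab, fdr)
  structure(list(tested = unname(attr(calls, "tested")[1L]),
                 significant = sum(calls$called),
                 n_loci = n_loci, fdr = fdr, table = tab),
            class = "null_sim_result")
}

#' Proportion of true-positive psADE calls
#'
#' Extrapolates the null simulator's significant fraction to the observed
#' number of tested loci to obtain the expected number of noise calls;
#' the true-positive proportion is `1 - expected_noise / observed_calls`,
#' clamped to [0, 1]. With zero null significants the proportion is 1; with
#' zero observed calls it is undefined (`NA` with a warning).
#'
#' @param observed_tested,observed_significant counts from the real data.
#' @param null_tested,null_significant counts from [null_fdr_run()].
#' @return a proportion in [0, 1], or `NA`.
#' @export
true_positive_proportion <- function(observed_tested, observed_significant,
                                     null_tested, null_significant) {
  stopifnot(observed_tested > 0, null_tested > 0)
  if (observed_significant == 0) {
    warning("no observed psADE calls; true-positive proportion undefined")
    return(NA_real_)
  }
  if (null_significant == 0) return(1)
  expected_noise <- null_significant / null_tested * observed_tested
  max(0, min(1, 1 - expected_noise / observed_significant))
}
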