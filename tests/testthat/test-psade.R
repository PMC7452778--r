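test_that("Fisher exact p values match hand-enumerated tables", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10), 2 / choose(20, 10))
  expect_equal(fisher_exact_2x2(2, 0, 0, 2), 1 / 3)
  expect_error(fisher_exact_2x2(0, 0, 5, 5), "not testable")
  expect_error(fisher_exact_2x2(5, 5, 0, 0), "not testable")
  expect_error(fisher_exact_2x2(-1, 5, 5, 5), "non-negative")
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
  set.seed(11)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(3:25, 1)), 2)
    if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0) next
    expect_equal(fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.2, 1.4)), "\\[0, 1\\]")

  set.seed(12)
  for (i in 1:30) {
    p <- runif(sample(1:80, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p))
    # invariance under permutation of input order
    o <- sample(seq_along(p))
    expect_equal(bh_adjust(p[o]), q[o])
  }
})

test_that("the detector tests heterozygous expressed loci and calls by q", {
  tab <- make_table(rbind(c(50, 50, 50, 50),
                          c(50, 50, 95, 5),
                          c(100, 0, 50, 50),   # homozygous: skipped
                          c(50, 50, 0, 0)))    # unexpressed: skipped
  calls <- detect_psade(tab, fdr = 0.05)
  expect_equal(unname(attr(calls, "tested")), 2L)
  expect_equal(calls$locus_id, c("L1", "L2"))
  expect_equal(calls$called, c(FALSE, TRUE))
  # q values are BH over the two tested loci of this population
  p2 <- fisher_exact_2x2(50, 50, 95, 5)
  expect_equal(calls$q, bh_adjust(c(fisher_exact_2x2(50, 50, 50, 50), p2)))
  expect_lt(p2, 1e-10)
  expect_equal(calls$d[2], 0.5 - 0.05)
  # locus 1 is an exact tie (BARE = BAF): favoured allele undefined
  expect_equal(calls$favored_allele, c(NA, "A"))
})

test_that("a transcriptome copying the genome yields no calls", {
  set.seed(13)
  for (i in 1:3) {
    g <- matrix(rpois(40 * 2, 25), 40, 2)
    tab <- make_table(cbind(g[, 1], g[, 2], g[, 1], g[, 2]))
    calls <- detect_psade(tab, fdr = 0.5)
    expect_equal(sum(calls$called), 0L)
  }
})

test_that("call counts shrink as the FDR threshold tightens", {
  cfg <- synth_config(n_pops = 2, n_loci = 2000, psade_fraction = 0.05,
                      psade_shift = 0.35, coverage_mu = 50,
                      coverage_theta = 13, selected_fraction = 0, seed = 14)
  tab <- generate_table(cfg)$table
  n_calls <- vapply(c(0.2, 0.05, 0.01),
                    function(a) sum(detect_psade(tab, a)$called), numeric(1))
  expect_true(all(diff(n_calls) <= 0))
})

test_that("Gaussian fit of D is the ML fit", {
  r <- fit_d_gaussian(c(0, 0, 0))
  expect_true(r$degenerate)
  expect_equal(c(r$mu, r$sigma), c(0, 0))

  r2 <- fit_d_gaussian(c(-0.1, 0.1))
  expect_equal(c(r2$mu, r2$sigma), c(0, 0.1))  # ML sd uses denominator N

  set.seed(15)
  d <- rnorm(1e4, 0, 0.05)
  r3 <- fit_d_gaussian(d)
  expect_lt(abs(r3$mu), 0.005)
  expect_lt(abs(r3$sigma / 0.05 - 1), 0.1)

  # agrees with the generic ML fitter
  ref <- fitdistrplus::fitdist(d, "norm")
  expect_equal(r3$mu, unname(ref$estimate["mean"]), tolerance = 1e-6)
  expect_equal(r3$sigma, unname(ref$estimate["sd"]), tolerance = 1e-6)
})

test_that("BAF-BARE regression recovers a planted linear relation", {
  baf <- seq(0.1, 0.9, length.out = 50)
  r <- baf_bare_regression(baf, baf)
  expect_equal(c(r$slope, r$intercept, r$r), c(1, 0, 1))

  rc <- baf_bare_regression(baf, rep(0.5, 50))
  expect_equal(rc$slope, 0)
  expect_true(is.na(rc$r))

  set.seed(16)
  bare <- 0.9 * baf + 0.05 + rnorm(50, 0, 0.02)
  rn <- baf_bare_regression(baf, bare)
  expect_lt(abs(rn$slope - 0.9), 0.05)
  expect_error(baf_bare_regression(rep(0.5, 10), runif(10)), "variance")
})
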