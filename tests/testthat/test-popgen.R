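test_that("allele fractions handle zeros and undefined denominators", {
  expect_equal(allele_fraction(5, 5), 0.5)
  expect_equal(allele_fraction(0, 10), 0)
  expect_true(is.na(allele_fraction(0, 0)))
  expect_equal(allele_fraction(c(1, 0), c(1, 0)), c(0.5, NA))
  expect_error(allele_fraction(-1, 2), "non-negative")
})

test_that("global F_ST matches the moment formula and its bounds", {
  expect_equal(global_fst(c(0.5, 0.5, 0.5)), 0)
  expect_equal(global_fst(c(0, 1)), 1)
  expect_equal(global_fst(c(0.2, 0.4)), 0.01 / 0.21)
  expect_true(is.na(global_fst(c(0, 0))))  # monomorphic: undefined
  expect_error(global_fst(0.5), "at least two")

  # vectorised version agrees with the scalar one and stays in [0, 1]
  set.seed(41)
  m <- matrix(runif(300), 50, 6)
  v <- fst_per_locus(m)
  expect_equal(v, apply(m, 1, global_fst), ignore_attr = TRUE)
  expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
})

test_that("LK statistic scales F_ST to mean n - 1 exactly", {
  expect_equal(lk_statistic(c(0.1, 0.1, 0.1), 7), c(6, 6, 6))
  expect_equal(lk_statistic(c(0.1, 0.3), 3), c(1, 3))
  set.seed(42)
  f <- rexp(1000)
  expect_equal(mean(lk_statistic(f, 7)), 6, tolerance = 1e-12)
  expect_error(lk_statistic(c(0, 0), 5), "positive")
})

test_that("pairwise F_ST is symmetric with zero diagonal and correct medians", {
  f <- matrix(c(0, 0, 0.5,
                1, 1, 0.5), ncol = 2,
              dimnames = list(paste0("L", 1:3), c("A", "B")))
  pw <- pairwise_fst(f)
  expect_equal(pw["A", "B"], 1)  # median of {1, 1, 0}
  expect_equal(diag(pw), c(A = 0, B = 0))

  same <- cbind(f[, 1], f[, 1], f[, 1])
  expect_true(all(pairwise_fst(same) == 0))

  set.seed(43)
  r <- matrix(runif(200), 40, 5)
  expect_equal(pairwise_fst(r), t(pairwise_fst(r)))
})

test_that("a table compared against itself has zero pairwise differentiation", {
  set.seed(44)
  pm <- matrix(rpois(30 * 4, 12), 30, 4)
  tab <- make_table(pm, pm)
  baf <- freq_matrix(tab)$baf
  expect_true(all(pairwise_fst(baf)[!is.na(pairwise_fst(baf))] == 0))
})

test_that("dip test separates unimodal from bimodal samples", {
  set.seed(5)
  x_uni <- rnorm(500)
  x_bi <- c(rnorm(250, -5), rnorm(250, 5))
  r_uni <- dip_unimodality_test(x_uni, n_boot = 200, seed = 6)
  r_bi <- dip_unimodality_test(x_bi, n_boot = 200, seed = 6)
  expect_gt(r_uni$p_value, 0.05)
  expect_lt(r_bi$p_value, 0.01)
  expect_gt(r_bi$statistic, r_uni$statistic)

  cst <- dip_unimodality_test(rep(1, 50), n_boot = 100)
  expect_equal(cst$statistic, 0)
  expect_equal(cst$p_value, 1)
  expect_error(dip_unimodality_test(rnorm(5)), "at least 10")
})

test_that("the split-point search finds the same dip as a full scan", {
  full_scan <- function(x) {
    x <- sort(x)
    n <- length(x)
    el <- sapply(seq_len(n), function(m) psade:::.gcm_deviation(x, m, n))
    er <- sapply(seq_len(n), function(m) psade:::.lcm_deviation(x, m, n))
    min(pmax(el, er)) / 2
  }
  set.seed(7)
  for (i in 1:40) {
    x <- switch(1 + i %% 4,
                runif(25), rnorm(25),
                c(rnorm(12, -3), rnorm(13, 3)),
                rbeta(25, 0.3, 0.3))
    expect_equal(dip_statistic(x), full_scan(x))
  }
})

test_that("Mantel test: identity, degenerate and exact-enumeration cases", {
  set.seed(8)
  d <- as.matrix(dist(matrix(runif(10), 5)))
  expect_equal(mantel_test(d, d, n_perm = 99)$r, 1)

  flat <- matrix(1, 5, 5); diag(flat) <- 0
  r <- mantel_test(d, flat, n_perm = 99)
  expect_true(is.na(r$r))
  expect_equal(r$p, 1)

  # 4 x 4: all 24 permutations enumerated; p equals the exact fraction
  d1 <- as.matrix(dist(c(0, 1, 3, 7)))
  d2 <- as.matrix(dist(c(0, 1.2, 2.6, 7.5)))
  res <- mantel_test(d1, d2, n_perm = 100)
  expect_equal(res$n_perm_used, 24)
  ut <- upper.tri(d1)
  rs <- vapply(oracle_permutations(4),
               function(p) cor(d1[ut], d2[p, p][ut]), numeric(1))
  expect_equal(res$p, mean(rs >= res$r - 1e-12))

  expect_error(mantel_test(d1, flat, 99), "matching dimension")
})

test_that("Mantel r agrees with vegan's statistic", {
  skip_if_not_installed("vegan")
  set.seed(9)
  a <- as.matrix(dist(matrix(runif(14), 7)))
  b <- as.matrix(dist(matrix(runif(14), 7)))
  ours <- mantel_test(a, b, n_perm = 199, seed = 1)
  ref <- vegan::mantel(a, b, permutations = 199)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("geographic distances: great-circle values and symmetry", {
  meta <- data.frame(population_id = c("A", "B", "C"),
                     latitude = c(0, 0, 45),
                     longitude = c(0, 1, 0))
  gd <- geo_distance_matrix(meta)
  expect_equal(gd, t(gd))
  expect_equal(diag(gd), c(A = 0, B = 0, C = 0))
  # one degree of longitude at the equator is ~111.3 km
  expect_equal(gd["A", "B"], 111.3, tolerance = 0.01)
  eu <- geo_distance_matrix(meta, method = "euclidean")
  expect_equal(eu["A", "B"], 1)
})
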