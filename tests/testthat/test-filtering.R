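# helper: a one-population table with given genomic depths (all reads on
# allele A) and token expression
depth_table <- function(depths, ...) {
  n <- length(depths)
  make_table(cbind(depths, 0L, 1L, 1L), ...)
}

test_that("co-abundance clustering isolates the co-abundant species cluster", {
  set.seed(21)
  # 40 loci near depth (30, 30, 30) across three populations, 5 outliers
  main <- matrix(sample(27:33, 40 * 3, replace = TRUE), 40, 3)
  odd <- cbind(rpois(5, 300), rpois(5, 5), rpois(5, 40))
  depths <- rbind(main, odd)
  pops <- lapply(1:3, function(j) cbind(depths[, j], 0L, 1L, 1L))
  tab <- do.call(make_table, pops)
  cl <- cluster_by_coabundance(tab, eps = 10, min_pts = 10)
  expect_equal(sort(cl$largest_loci), sort(paste0("L", 1:40)))

  # oracle: density reachability with brute-force pairwise distances
  truth <- oracle_density_clusters(depths, eps = 10, min_pts = 10)
  main_comp <- truth[[which.max(lengths(truth))]]
  expect_setequal(match(cl$largest_loci, tab$locus_ids), main_comp)
})

test_that("clustering degenerate cases: identical vectors and tiny tables", {
  tab <- depth_table(rep(30L, 15))
  cl <- cluster_by_coabundance(tab, eps = 10, min_pts = 10)
  expect_equal(unname(cl$labels), rep(1L, 15))
  expect_length(cl$largest_loci, 15)

  small <- depth_table(c(10L, 300L, 600L))
  cl2 <- cluster_by_coabundance(small, eps = 10, min_pts = 10)
  expect_true(all(cl2$labels == 0L))
  expect_true(is.na(cl2$largest))
})

test_that("depth window combines median +/- n_sigma*sd with hard bounds", {
  tab <- depth_table(c(8L, 10L, 12L, 10L, 10L, 60L))
  # median 10, sample sd ~20.45 -> window [max(5, -30.9), min(150, 50.9)]
  expect_equal(depth_filter(tab, filter_config()), paste0("L", 1:5))

  # constant depth: sd 0, window collapses onto the median
  allsame <- depth_table(rep(30L, 4))
  expect_equal(depth_filter(allsame, filter_config()), paste0("L", 1:4))

  # a locus below min_depth_all in one population is removed even if the
  # window would admit it
  two <- make_table(cbind(c(3L, 10L, 10L, 10L), 0L, 1L, 1L),
                    cbind(rep(10L, 4), 0L, 1L, 1L))
  cfg <- filter_config(min_depth_all = 4, min_cov = 0, max_cov = Inf,
                       n_sigma = 100)
  expect_equal(depth_filter(two, cfg), paste0("L", 2:4))

  empty_pop <- make_table(cbind(c(10L, 10L), 0L, 1L, 1L),
                          cbind(c(0L, 0L), 0L, 1L, 1L))
  expect_error(depth_filter(empty_pop), "P2")
})

test_that("frequency filter needs BAF and BARE in range in the same population", {
  # BAF = BARE = 0.5 in one of three populations -> kept
  loc_ok <- list(c(10, 0, 5, 0), c(5, 5, 5, 5), c(0, 10, 0, 5))
  # BAF = 0.95 everywhere -> removed
  loc_baf <- list(c(1, 19, 1, 19), c(1, 19, 1, 19), c(1, 19, 1, 19))
  # heterozygous but never expressed (BARE undefined) -> removed
  loc_noexpr <- list(c(5, 5, 0, 0), c(5, 5, 0, 0), c(5, 5, 0, 0))
  pops <- lapply(1:3, function(j) {
    rbind(loc_ok[[j]], loc_baf[[j]], loc_noexpr[[j]])
  })
  tab <- do.call(make_table, pops)
  expect_equal(frequency_filter(tab, filter_config()), "L1")
})

test_that("filters are idempotent and monotone in their windows", {
  set.seed(31)
  pops <- lapply(1:2, function(j) matrix(rpois(50 * 4, 15), 50, 4))
  tab <- do.call(make_table, pops)
  cfg <- filter_config()

  s1 <- depth_filter(tab, cfg)
  tab1 <- subset_count_table(tab, loci = s1)
  # re-applying on the survivor set with the same absolute window bounds
  # cannot resurrect loci; with wide sigma it keeps them all
  wide <- filter_config(min_depth_all = 0, min_cov = 0, max_cov = Inf,
                        n_sigma = 1e6)
  expect_equal(depth_filter(tab1, wide), s1)

  f1 <- frequency_filter(tab, cfg)
  expect_equal(frequency_filter(subset_count_table(tab, loci = f1), cfg), f1)

  # widening the BAF/BARE windows never removes a survivor
  wider <- filter_config(baf_lo = 0.01, baf_hi = 0.99,
                         bare_lo = 0.01, bare_hi = 0.99)
  expect_true(all(f1 %in% frequency_filter(tab, wider)))

  # fully open depth filter keeps every locus
  expect_equal(depth_filter(tab, wide), tab$locus_ids)
})
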