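test_that("overlap test matches the worked hypergeometric example", {
  # universe of 10, 4 selected, 5 psADE, overlap 3:
  # P(X >= 3) = (C(4,3) C(6,2) + C(4,4) C(6,1)) / C(10,5) = 66/252
  sel <- selection_calls(paste0("L", 1:10), paste0("L", 1:4))
  ht <- hypergeom_overlap_test(c("L1", "L2", "L3", "L7", "L8"), sel)
  expect_equal(ht$q, 3L)
  expect_equal(ht$m, 4L)
  expect_equal(ht$n, 6L)
  expect_equal(ht$k, 5L)
  expect_equal(ht$p, 66 / 252)

  # zero overlap short-circuits to 1
  ht0 <- hypergeom_overlap_test(c("L9", "L10"), sel)
  expect_equal(ht0$p, 1)

  # psADE = whole universe forces q = m and p = 1
  htall <- hypergeom_overlap_test(paste0("L", 1:10), sel)
  expect_equal(htall$q, htall$m)
  expect_equal(htall$p, 1)

  expect_warning(hypergeom_overlap_test(c("L1", "OUT"), sel), "dropped")
  expect_error(selection_calls(character(), character()), "empty universe")
  expect_error(selection_calls("L1", "L2"), "subset")
})

test_that("overlap p equals enumeration on a randomized sweep of small universes", {
  set.seed(26)
  for (i in 1:150) {
    N <- sample(2:25, 1)
    m <- sample(0:N, 1)
    k <- sample(0:N, 1)
    uni <- paste0("U", seq_len(N))
    sel <- selection_calls(uni, uni[seq_len(m)])
    qs <- max(0, k - (N - m)):min(m, k)
    q <- qs[sample.int(length(qs), 1)]
    psade <- c(uni[seq_len(q)],
               if (k > q) uni[m + seq_len(k - q)])
    ht <- hypergeom_overlap_test(psade, sel)
    expect_equal(ht$q, q)
    expect_equal(ht$p, if (q == 0) 1 else oracle_hyper_upper(q, m, N - m, k))
  }
})

test_that("overlap p is monotone non-increasing in the overlap size", {
  m <- 8; n <- 12; k <- 9
  ps <- vapply(0:min(m, k), function(q) {
    if (q == 0) 1 else oracle_hyper_upper(q, m, n, k)
  }, numeric(1))
  uni <- paste0("U", 1:(m + n))
  sel <- selection_calls(uni, uni[1:m])
  impl <- vapply(max(0, k - n):min(m, k), function(q) {
    hypergeom_overlap_test(c(uni[seq_len(q)], uni[m + seq_len(k - q)]),
                           sel)$p
  }, numeric(1))
  expect_true(all(diff(impl) <= 1e-12))
})

test_that("category enrichment flags over-represented annotations", {
  bg <- paste0("L", 1:100)
  ann <- rbind(data.frame(locus_id = paste0("L", 1:10), category = "X"),
               data.frame(locus_id = paste0("L", 1:50), category = "Y"))
  cand <- paste0("L", 1:5)  # all five in X
  res <- enrichment_test(cand, bg, ann)
  x <- res[res$category == "X", ]
  expect_equal(x$count, 5L)
  expect_equal(x$p, oracle_hyper_upper(5, 10, 90, 5))
  expect_true(x$enriched)
  expect_equal(x$expected, 5 * 10 / 100)

  # candidate = background: nothing can be enriched
  resall <- enrichment_test(bg, bg, ann)
  expect_true(all(resall$p == 1))

  # category with no candidate member
  res2 <- enrichment_test(c("L60", "L70"), bg, ann)
  expect_equal(res2$p[res2$category == "X"], 1)

  expect_warning(
    enrichment_test(cand, bg, rbind(ann,
      data.frame(locus_id = "ZZZ", category = "ghost"))), "ghost")
  expect_error(enrichment_test("nope", bg, ann), "subset")
})

test_that("selection TSVs are accepted in q-value and flag form", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus_id\tqvalue", "L1\t0.01", "L2\t0.2", "L3\t0.04"), path)
  sel <- read_selection_calls(path, q_threshold = 0.05)
  expect_setequal(sel$selected, c("L1", "L3"))
  expect_length(sel$universe, 3)

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus_id\tflag", "L1\t1", "L2\t0"), path2)
  sel2 <- read_selection_calls(path2)
  expect_equal(sel2$selected, "L1")
})
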