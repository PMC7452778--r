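test_that("TSV count tables read back exactly what was written", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus_id\tP1.GA\tP1.GB\tP1.TA\tP1.TB",
               "L1\t5\t5\t8\t2",
               "L2\t10\t0\t7\t0"), path)
  tab <- read_count_table(path)
  expect_equal(tab$locus_ids, c("L1", "L2"))
  expect_equal(tab$population_ids, "P1")
  expect_equal(unname(c(tab$ga["L1", 1], tab$gb["L1", 1],
                        tab$ta["L1", 1], tab$tb["L1", 1])), c(5L, 5L, 8L, 2L))
  expect_equal(unname(tab$ga["L2", 1]), 10L)

  # round trip preserves every cell
  out <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab, out)
  tab2 <- read_count_table(out)
  expect_identical(tab[c("ga", "gb", "ta", "tb")],
                   tab2[c("ga", "gb", "ta", "tb")])
})

test_that("round trip holds for randomly generated tables", {
  set.seed(99)
  for (i in 1:5) {
    n <- sample(1:30, 1)
    k <- sample(1:4, 1)
    mats <- replicate(k, matrix(rpois(n * 4, 20), n, 4), simplify = FALSE)
    tab <- do.call(make_table, mats)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_count_table(tab, path)
    back <- read_count_table(path)
    expect_identical(back[c("ga", "gb", "ta", "tb")],
                     tab[c("ga", "gb", "ta", "tb")])
  }
})

test_that("header-only files give an empty table; layout has 4 columns per population", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("locus_id\tA.GA\tA.GB\tA.TA\tA.TB", path)
  tab <- read_count_table(path)
  expect_length(tab$locus_ids, 0)
  expect_equal(tab$population_ids, "A")

  # three populations -> 12 count columns in declared block order
  tab3 <- make_table(matrix(1:4, 1), matrix(5:8, 1), matrix(9:12, 1))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab3, out)
  header <- strsplit(readLines(out)[1], "\t")[[1]]
  expect_length(header, 13)
  expect_equal(header[2:5], c("P1.GA", "P1.GB", "P1.TA", "P1.TB"))
  expect_equal(header[10:13], c("P3.GA", "P3.GB", "P3.TA", "P3.TB"))
})

test_that("strict parsing reports locus and column; structural errors are named", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus_id\tP1.GA\tP1.GB\tP1.TA\tP1.TB",
               "L1\t5\tx\t8\t2"), path)
  expect_error(read_count_table(path), "L1.*column 3")

  # missing column in a population block names the population
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus_id\tP1.GA\tP1.GB\tP1.TA\tP2.TB", "L1\t1\t1\t1\t1"), path2)
  expect_error(read_count_table(path2), "P1")

  # duplicated locus id
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus_id\tP1.GA\tP1.GB\tP1.TA\tP1.TB",
               "L1\t1\t1\t1\t1", "L1\t2\t2\t2\t2"), path3)
  expect_error(read_count_table(path3), "duplicate locus")
})

test_that("validation reports violations without throwing", {
  tab <- make_table(matrix(c(5, 5, 8, 2), 1))
  expect_length(validate_count_table(tab), 0)

  bad <- tab
  bad$ga[1, 1] <- -1L
  v <- validate_count_table(bad)
  expect_length(v, 1)
  expect_match(v, "G_A.*L1.*P1")

  dup <- tab
  dup$locus_ids <- c("L1")
  dup2 <- make_table(matrix(rep(1, 8), 2, 4, byrow = TRUE),
                     locus_ids = c("LX", "LX"))
  expect_match(validate_count_table(dup2), "duplicate locus id: LX", all = FALSE)
})

test_that("population metadata is read and range-checked", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("population_id\tlatitude\tlongitude",
               "P1\t79.5\t11.0", "P2\t-60.2\t-55.9"), path)
  meta <- read_population_meta(path)
  expect_equal(meta$population_id, c("P1", "P2"))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("population_id\tlatitude\tlongitude", "P1\t95\t0"), bad)
  expect_error(read_population_meta(bad), "latitude")
})
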