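# Locus selection: co-abundance clustering to isolate the loci of a single
# species from a mixed-community variant set, depth-of-coverage windows to
# drop low-covered and multicopy regions, and allele-frequency /
# relative-expression range filters to drop rare alleles and calling
# errors.

#' Filtering configuration
#'
#' Bundles the thresholds of the locus-selection procedure. Defaults follow
#' the standard pooled-sample workflow: at least 4x genomic depth in every
#' population, per-population coverage within median +/- 2 sigma further
#' clamped to [5, 150], B-allele frequency (BAF) in [0.1, 0.9] together
#' with B-allele relative expression (BARE) in [0.05, 0.95] in at least one
#' population, and density-based co-abundance clustering with eps = 10,
#' minPts = 10.
#'
#' @param min_depth_all minimum genomic depth required in every population.
#' @param min_cov,max_cov hard lower/upper coverage bounds clamping the
#'   median +/- `n_sigma`*sd window.
#' @param n_sigma width of the coverage window in standard deviations.
#' @param baf_lo,baf_hi BAF range (inclusive).
#' @param bare_lo,bare_hi BARE range (inclusive).
#' @param cluster_eps,cluster_min_pts DBSCAN parameters for co-abundance
#'   clustering.
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(min_depth_all = 4L, min_cov = 5L, max_cov = 150L,
                          n_sigma = 2, baf_lo = 0.1, baf_hi = 0.9,
                          bare_lo = 0.05, bare_hi = 0.95,
                          cluster_eps = 10, cluster_min_pts = 10L) {
  .assert_scalar_number(min_depth_all, "min_depth_all", 0)
  .assert_scalar_number(min_cov, "min_cov", 0)
  .assert_scalar_number(max_cov, "max_cov", min_cov)
  .assert_scalar_number(n_sigma, "n_sigma")
  if (n_sigma <= 0) stop("n_sigma must be > 0", call. = FALSE)
  .assert_scalar_number(baf_lo, "baf_lo", 0, 1)
  .assert_scalar_number(baf_hi, "baf_hi", baf_lo, 1)
  if (baf_lo >= baf_hi) stop("need baf_lo < baf_hi", call. = FALSE)
  .assert_scalar_number(bare_lo, "bare_lo", 0, 1)
  .assert_scalar_number(bare_hi, "bare_hi", bare_lo, 1)
  if (bare_lo >= bare_hi) stop("need bare_lo < bare_hi", call. = FALSE)
  .assert_scalar_number(cluster_eps, "cluster_eps", 0)
  .assert_scalar_number(cluster_min_pts, "cluster_min_pts", 1)
  structure(list(min_depth_all = min_depth_all, min_cov = min_cov,
                 max_cov = max_cov, n_sigma = n_sigma, baf_lo = baf_lo,
                 baf_hi = baf_hi, bare_lo = bare_lo, bare_hi = bare_hi,
                 cluster_eps = cluster_eps, cluster_min_pts = cluster_min_pts),
            class = "filter_config")
}

# Classic DBSCAN on a numeric feature matrix (rows = points), Euclidean
# distance. Label 0 is noise. Deterministic given row order: clusters are
# seeded in row order and neighbourhoods expanded breadth-first. A point's
# eps-neighbourhood includes the point itself (so a core point needs
# min_pts - 1 *other* points within eps).
.dbscan <- function(X, eps, min_pts) {
  n <- nrow(X)
  d2 <- as.matrix(stats::dist(X))
  nbr <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps))
  core <- vapply(nbr, length, integer(1)) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nbr[[i]], i)
    while (length(queue)) {
      j <- queue[[1L]]
      queue <- queue[-1L]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, setdiff(nbr[[j]], which(labels != 0L)))
      }
    }
  }
  labels
}

#' Cluster loci by genomic co-abundance
#'
#' Groups loci by the similarity of their per-population genomic depth
#' profile with density-based clustering (DBSCAN, Euclidean distance on the
#' raw depth vectors). Loci of a single abundant species co-vary across
#' samples and form one large cluster; loci from other organisms or
#' multicopy regions fall into other clusters or noise.
#'
#' @param x a [count_table()].
#' @param eps DBSCAN neighbourhood radius (depth units).
#' @param min_pts DBSCAN core-point threshold.
#' @return a list with `labels` (integer vector named by locus, 0 = noise),
#'   `largest` (label of the most populous cluster, `NA` if every locus is
#'   noise), and `largest_loci` (locus ids of the largest cluster).
#' @export
cluster_by_coabundance <- function(x, eps = 10, min_pts = 10L) {
  stopifnot(inherits(x, "count_table"))
  if (!length(x$locus_ids)) stop("empty count table", call. = FALSE)
  depth <- genomic_depth(x)
  labels <- .dbscan(depth, eps, min_pts)
  names(labels) <- x$locus_ids
  clusters <- labels[labels > 0L]
  if (!length(clusters)) {
    return(list(labels = labels, largest = NA_integer_,
                largest_loci = character()))
  }
  sizes <- table(clusters)
  largest <- as.integer(names(sizes)[which.max(sizes)])
  list(labels = labels, largest = largest,
       largest_loci = x$locus_ids[labels == largest])
}

#' Depth-of-coverage filter
#'
#' A locus survives iff in every population its genomic depth lies inside
#' `[max(min_cov, median - n_sigma*sd), min(max_cov, median + n_sigma*sd)]`
#' and is at least `min_depth_all`. The per-population median and sample
#' standard deviation are computed over all loci of the table actually
#' passed in, so the window reflects the post-clustering universe.
#'
#' @param x a [count_table()].
#' @param cfg a [filter_config()].
#' @return character vector of surviving locus ids.
#' @export
depth_filter <- function(x, cfg = filter_config()) {
  stopifnot(inherits(x, "count_table"), inherits(cfg, "filter_config"))
  if (!length(x$locus_ids)) stop("empty count table", call. = FALSE)
  depth <- genomic_depth(x)
  keep <- rep(TRUE, nrow(depth))
  for (j in seq_along(x$population_ids)) {
    d <- depth[, j]
    if (sum(d) == 0L) {
      stop("population '", x$population_ids[j],
           "' has zero genomic depth at every locus", call. = FALSE)
    }
    med <- stats::median(d)
    s <- stats::sd(d)
    if (is.na(s)) s <- 0
    lo <- max(cfg$min_cov, med - cfg$n_sigma * s)
    hi <- min(cfg$max_cov, med + cfg$n_sigma * s)
    keep <- keep & d >= cfg$min_depth_all & d >= lo & d <= hi
  }
  x$locus_ids[keep]
}

#' Allele-frequency / relative-expression range filter
#'
#' Keeps loci for which at least one population has, simultaneously, a
#' defined BAF within `[baf_lo, baf_hi]` and a defined BARE within
#' `[bare_lo, bare_hi]`. Undefined fractions (zero depth or zero
#' expression) fail the condition in that population.
#'
#' @inheritParams depth_filter
#' @return character vector of surviving locus ids.
#' @export
frequency_filter <- function(x, cfg = filter_config()) {
  stopifnot(inherits(x, "count_table"), inherits(cfg, "filter_config"))
  fm <- freq_matrix(x)
  ok <- !is.na(fm$baf) & fm$baf >= cfg$baf_lo & fm$baf <= cfg$baf_hi &
    !is.na(fm$bare) & fm$bare >= cfg$bare_lo & fm$bare <= cfg$bare_hi
  x$locus_ids[rowSums(ok) > 0L]
}

#' Run the full locus-selection procedure
#'
#' Convenience wrapper: co-abundance clustering (keep the largest cluster),
#' then the depth window, then the BAF/BARE range filter.
#'
#' @inheritParams depth_filter
#' @param cluster run the co-abundance clustering step (disable for data
#'   already restricted to one species).
#' @return the filtered [count_table()].
#' @export
filter_loci <- function(x, cfg = filter_config(), cluster = TRUE) {
  stopifnot(inherits(x, "count_table"))
  if (cluster) {
    cl <- cluster_by_coabundance(x, cfg$cluster_eps, cfg$cluster_min_pts)
    if (is.na(cl$largest)) stop("co-abundance clustering found no cluster",
                                call. = FALSE)
    x <- subset_count_table(x, loci = cl$largest_loci)
  }
  x <- subset_count_table(x, loci = depth_filter(x, cfg))
  subset_count_table(x, loci = frequency_filter(x, cfg))
}
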