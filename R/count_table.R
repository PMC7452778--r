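# Canonical container for paired metagenomic/metatranscriptomic allele
# counts: for every locus and population, four non-negative integers
# (G_A, G_B) genomic and (T_A, T_B) transcriptomic reads supporting the
# two alleles of a biallelic site. Allele "A" is the arbitrarily oriented
# first allele of the reference-free caller; "B" the alternative. The
# package never reorients alleles. Absence of coverage is stored as zero
# counts, never as missing values; downstream statistics decide
# eligibility.

#' Construct a count table
#'
#' @param ga,gb,ta,tb integer matrices (loci x populations) of read counts
#'   supporting allele A/B at the genomic (`ga`, `gb`) and transcriptomic
#'   (`ta`, `tb`) level. All four must share dimensions; row names are locus
#'   ids and column names population ids.
#' @return an object of class `count_table`: a list with elements `ga`,
#'   `gb`, `ta`, `tb` (integer matrices) plus `locus_ids` and
#'   `population_ids`.
#' @examples
#' m <- function(x) matrix(as.integer(x), 2, 1,
#'                         dimnames = list(c("L1", "L2"), "P1"))
#' tab <- count_table(m(c(5, 10)), m(c(5, 0)), m(c(8, 7)), m(c(2, 0)))
#' genomic_depth(tab)
#' @export
count_table <- function(ga, gb, ta, tb) {
  mats <- list(ga = ga, gb = gb, ta = ta, tb = tb)
  dims <- lapply(mats, dim)
  if (length(unique(dims)) != 1L) {
    stop("ga, gb, ta, tb must have identical dimensions", call. = FALSE)
  }
  mats <- lapply(mats, function(m) {
    storage.mode(m) <- "integer"
    m
  })
  locus_ids <- rownames(mats$ga)
  pop_ids <- colnames(mats$ga)
  if (is.null(locus_ids)) locus_ids <- if (nrow(mats$ga)) paste0("L", seq_len(nrow(mats$ga))) else character()
  if (is.null(pop_ids)) pop_ids <- if (ncol(mats$ga)) paste0("P", seq_len(ncol(mats$ga))) else character()
  mats <- lapply(mats, function(m) {
    dimnames(m) <- list(locus_ids, pop_ids)
    m
  })
  structure(c(mats, list(locus_ids = locus_ids, population_ids = pop_ids)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d loci x %d populations\n",
              length(x$locus_ids), length(x$population_ids)))
  if (length(x$population_ids)) {
    cat("populations:", paste(x$population_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset a count table by loci and/or populations
#'
#' @param x a `count_table`.
#' @param loci locus ids or indices (default: all).
#' @param pops population ids or indices (default: all).
#' @return a `count_table`.
#' @export
subset_count_table <- function(x, loci = NULL, pops = NULL) {
  stopifnot(inherits(x, "count_table"))
  if (is.null(loci)) loci <- x$locus_ids
  if (is.null(pops)) pops <- x$population_ids
  count_table(x$ga[loci, pops, drop = FALSE], x$gb[loci, pops, drop = FALSE],
              x$ta[loci, pops, drop = FALSE], x$tb[loci, pops, drop = FALSE])
}

#' Per-locus, per-population genomic depth and expression level
#'
#' Genomic depth is `G_A + G_B`; expression level is `T_A + T_B`. Both are
#' derived quantities, never stored.
#'
#' @param x a `count_table`.
#' @return an integer matrix (loci x populations).
#' @export
genomic_depth <- function(x) {
  stopifnot(inherits(x, "count_table"))
  x$ga + x$gb
}

#' @rdname genomic_depth
#' @export
expression_level <- function(x) {
  stopifnot(inherits(x, "count_table"))
  x$ta + x$tb
}

.block_suffixes <- c("GA", "GB", "TA", "TB")

#' Read a count table from TSV
#'
#' The canonical on-disk format is a UTF-8 tab-separated table with a header
#' row: column `locus_id`, then for every population `P` the four columns
#' `P.GA`, `P.GB`, `P.TA`, `P.TB` in that order. Lines starting with `#` are
#' ignored. Parsing is strict: any count cell that is not a plain integer is
#' an error naming the offending locus and column.
#'
#' @param path path to an existing TSV file.
#' @return a [count_table()].
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count table file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("count table file is empty (no header): ", path, call. = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (header[[1L]] != "locus_id") {
    stop("count table header must start with 'locus_id', got '", header[[1L]], "'",
         call. = FALSE)
  }
  count_cols <- header[-1L]
  if (length(count_cols) %% 4L != 0L) {
    stop("count columns must come in blocks of 4 per population (GA, GB, TA, TB)",
         call. = FALSE)
  }
  pops <- character()
  if (length(count_cols)) {
    pop_of <- sub("\\.(GA|GB|TA|TB)$", "", count_cols)
    suf_of <- sub("^.*\\.", "", count_cols)
    pops <- unique(pop_of)
    for (p in pops) {
      have <- suf_of[pop_of == p]
      if (!identical(have, .block_suffixes)) {
        stop(sprintf(
          "population '%s': expected column block %s, found %s", p,
          paste0(p, ".", .block_suffixes, collapse = " "),
          paste(count_cols[pop_of == p], collapse = " ")), call. = FALSE)
      }
    }
  }
  body <- lines[-1L]
  n <- length(body)
  locus_ids <- character(n)
  cells <- matrix(NA_integer_, n, length(count_cols))
  for (i in seq_len(n)) {
    fields <- strsplit(body[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != length(header)) {
      stop(sprintf("row %d: expected %d fields, got %d", i, length(header),
                   length(fields)), call. = FALSE)
    }
    locus_ids[[i]] <- fields[[1L]]
    vals <- .strict_integer(fields[-1L])
    if (anyNA(vals)) {
      j <- which(is.na(vals))[[1L]]
      stop(sprintf("locus '%s': non-integer count in column %d ('%s')",
                   fields[[1L]], j + 1L, fields[[j + 1L]]), call. = FALSE)
    }
    cells[i, ] <- vals
  }
  if (anyDuplicated(locus_ids)) {
    stop("duplicate locus id(s): ",
         paste(unique(locus_ids[duplicated(locus_ids)]), collapse = ", "),
         call. = FALSE)
  }
  pick <- function(k) {
    m <- cells[, seq(k, by = 4L, length.out = length(pops)), drop = FALSE]
    dimnames(m) <- list(locus_ids, pops)
    m
  }
  if (!length(pops)) {
    empty <- matrix(integer(), n, 0L, dimnames = list(locus_ids, NULL))
    return(count_table(empty, empty, empty, empty))
  }
  count_table(pick(1L), pick(2L), pick(3L), pick(4L))
}

#' Write a count table to TSV
#'
#' Inverse of [read_count_table()]: `read_count_table(write_count_table(x))`
#' reproduces `x` cell for cell.
#'
#' @param x a `count_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  pops <- x$population_ids
  header <- c("locus_id",
              as.vector(t(outer(pops, .block_suffixes, paste, sep = "."))))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  if (length(x$locus_ids)) {
    blocks <- matrix("", length(x$locus_ids), 4L * length(pops))
    for (j in seq_along(pops)) {
      blocks[, 4L * j - 3L] <- x$ga[, j]
      blocks[, 4L * j - 2L] <- x$gb[, j]
      blocks[, 4L * j - 1L] <- x$ta[, j]
      blocks[, 4L * j] <- x$tb[, j]
    }
    writeLines(paste(x$locus_ids, apply(blocks, 1L, paste, collapse = "\t"),
                     sep = if (length(pops)) "\t" else ""), con)
  }
  invisible(path)
}

#' Validate a count table
#'
#' Checks every container invariant and reports violations without
#' throwing: all counts non-negative and non-missing, no duplicated locus
#' or population ids, matching dimensions.
#'
#' @param x a `count_table`.
#' @return a character vector of human-readable violations; empty when the
#'   table is valid.
#' @export
validate_count_table <- function(x) {
  out <- character()
  if (!inherits(x, "count_table")) return("not a count_table object")
  if (anyDuplicated(x$locus_ids)) {
    out <- c(out, paste0("duplicate locus id: ",
                         unique(x$locus_ids[duplicated(x$locus_ids)])))
  }
  if (anyDuplicated(x$population_ids)) {
    out <- c(out, paste0("duplicate population id: ",
                         unique(x$population_ids[duplicated(x$population_ids)])))
  }
  for (f in c("ga", "gb", "ta", "tb")) {
    m <- x[[f]]
    bad <- which(is.na(m) | m < 0L, arr.ind = TRUE)
    if (nrow(bad)) {
      out <- c(out, sprintf(
        "negative or missing %s count at locus '%s', population '%s'",
        toupper(sub("(.)(.)", "\\1_\\2", f)),
        x$locus_ids[bad[, 1L]], x$population_ids[bad[, 2L]]))
    }
  }
  out
}

#' Read population metadata (coordinates)
#'
#' TSV with header `population_id latitude longitude`; latitude in
#' [-90, 90] and longitude in [-180, 180] decimal degrees.
#'
#' @param path TSV file path.
#' @return a data.frame with columns `population_id`, `latitude`,
#'   `longitude`.
#' @export
read_population_meta <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("population_id", "latitude", "longitude")
  if (!all(need %in% names(df))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(df$latitude)) || any(abs(df$latitude) > 90)) {
    stop("latitude must be in [-90, 90]", call. = FALSE)
  }
  if (any(is.na(df$longitude)) || any(abs(df$longitude) > 180)) {
    stop("longitude must be in [-180, 180]", call. = FALSE)
  }
  if (anyDuplicated(df$population_id)) stop("duplicate population_id", call. = FALSE)
  df[need]
}
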