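# Interface to an external selection scan (e.g. a PCA-based outlier scan
# run on the allele-frequency matrix upstream) and the overlap /
# enrichment machinery: a hypergeometric test of the intersection between
# psADE calls and selection-flagged loci, and a generic category
# enrichment test for locus -> annotation tables.

#' Selection call set
#'
#' @param universe character vector of all locus ids tested by the scan.
#' @param selected character vector of loci flagged under selection
#'   (must be a subset of `universe`).
#' @return a list of class `selection_calls`.
#' @export
selection_calls <- function(universe, selected) {
  universe <- unique(as.character(universe))
  selected <- unique(as.character(selected))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (!all(selected %in% universe)) {
    stop("selected loci must be a subset of the universe", call. = FALSE)
  }
  structure(list(universe = universe, selected = selected),
            class = "selection_calls")
}

#' Read selection calls from TSV
#'
#' Two-column TSV `locus_id <tab> qvalue` (flagged iff `qvalue <
#' q_threshold`) or `locus_id <tab> flag` with flag in {0, 1}.
#'
#' @param path TSV path, with header.
#' @param q_threshold threshold applied when the second column is a q
#'   value.
#' @return a [selection_calls()] object.
#' @export
read_selection_calls <- function(path, q_threshold = 0.05) {
  if (!file.exists(path)) stop("selection file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("selection TSV needs two columns", call. = FALSE)
  val <- df[[2L]]
  flag <- if (all(val %in% c(0, 1))) val == 1 else val < q_threshold
  selection_calls(df[[1L]], df[[1L]][flag])
}

#' Hypergeometric test of the psADE x selection overlap
#'
#' Tests whether the overlap between a population's psADE calls and the
#' selection-flagged loci is larger than expected by chance: upper-tail
#' `P(X >= q)` for `X ~ Hypergeometric(m, n, k)` with `m` selected loci,
#' `n` unselected loci, `k` psADE loci in the universe and `q` the
#' observed intersection. psADE loci outside the scan's universe are
#' dropped with a warning.
#'
#' @param psade_ids character vector of loci under psADE in one
#'   population.
#' @param selection a [selection_calls()] object.
#' @return a list of class `intersection_test`: `q`, `m`, `n`, `k`, `p`.
#' @export
hypergeom_overlap_test <- function(psade_ids, selection) {
  stopifnot(inherits(selection, "selection_calls"))
  psade_ids <- unique(as.character(psade_ids))
  outside <- setdiff(psade_ids, selection$universe)
  if (length(outside)) {
    warning(length(outside), " psADE locus/loci outside the selection universe dropped")
    psade_ids <- intersect(psade_ids, selection$universe)
  }
  m <- length(selection$selected)
  n <- length(selection$universe) - m
  k <- length(psade_ids)
  q <- length(intersect(psade_ids, selection$selected))
  p <- if (q == 0) 1 else stats::phyper(q - 1, m, n, k, lower.tail = FALSE)
  structure(list(q = q, m = m, n = n, k = k, p = p),
            class = "intersection_test")
}

#' Annotation-category enrichment among candidate loci
#'
#' For each category, an upper-tail hypergeometric test of category
#' membership among the candidate loci against the background, BH-adjusted
#' across categories. Loci may carry several categories; categories with
#' no background member are skipped with a warning.
#'
#' @param candidate character vector of candidate locus ids (subset of
#'   `background`).
#' @param background character vector of background locus ids.
#' @param annotation data.frame with columns `locus_id` and `category`
#'   (one row per locus-category link).
#' @return a data.frame with `category`, `count` (candidates in the
#'   category), `size` (background members), `expected`, `p`, `q`,
#'   `enriched` (`q < 0.05`).
#' @export
enrichment_test <- function(candidate, background, annotation) {
  candidate <- unique(as.character(candidate))
  background <- unique(as.character(background))
  if (!all(candidate %in% background)) {
    stop("candidate loci must be a subset of the background", call. = FALSE)
  }
  stopifnot(all(c("locus_id", "category") %in% names(annotation)))
  ann <- annotation[annotation$locus_id %in% background, , drop = FALSE]
  dropped <- setdiff(unique(annotation$category), unique(ann$category))
  if (length(dropped)) {
    warning("category absent from background skipped: ",
            paste(dropped, collapse = ", "))
  }
  cats <- sort(unique(ann$category))
  N <- length(background)
  n_cand <- length(candidate)
  rows <- lapply(cats, function(cat) {
    members <- unique(ann$locus_id[ann$category == cat])
    K <- length(members)
    cnt <- length(intersect(candidate, members))
    p <- if (cnt == 0) 1 else stats::phyper(cnt - 1, K, N - K, n_cand,
                                            lower.tail = FALSE)
    data.frame(category = cat, count = cnt, size = K,
               expected = n_cand * K / N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(category = character(), count = integer(),
                      size = integer(), expected = numeric(), p = numeric(),
                      q = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE))
  }
  out$q <- bh_adjust(out$p)
  out$enriched <- out$q < 0.05
  out[order(out$p), , drop = FALSE]
}
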