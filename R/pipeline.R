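# End-to-end driver chaining the analysis stages: (synthetic) input ->
# locus filtering -> population-genetic summaries -> psADE detection ->
# null-model noise calibration -> shared-psADE vs differentiation model ->
# selection overlap -> annotation enrichment. Every stage writes TSV/JSON
# under one output directory and is recorded in a manifest; a rerun with
# the same configuration and seeds is bit-identical.

#' Assemble a pipeline configuration
#'
#' @param out_dir output directory (created if missing).
#' @param counts path to a count-table TSV (omit when `synth` is given).
#' @param synth optional list of [synth_config()] arguments; when present
#'   the pipeline generates its input and writes the truth labels.
#' @param filter list of [filter_config()] arguments.
#' @param cluster run the co-abundance clustering step during filtering.
#' @param fdr FDR threshold for psADE calls.
#' @param null_n_loci loci per population for the null simulator (0
#'   disables the noise-calibration stage).
#' @param geo optional population-metadata TSV for the Mantel test.
#' @param selection optional selection-scan TSV
#'   (see [read_selection_calls()]).
#' @param annotation optional locus-to-category TSV for enrichment.
#' @param seed root seed for every stochastic stage.
#' @return a list of class `run_config`.
#' @export
run_config <- function(out_dir, counts = NULL, synth = NULL,
                       filter = list(), cluster = FALSE, fdr = 0.05,
                       null_n_loci = 50000L, geo = NULL, selection = NULL,
                       annotation = NULL, seed = 1L) {
  .assert_scalar_number(fdr, "fdr", 0, 1)
  if (is.null(counts) && is.null(synth)) {
    stop("either 'counts' or 'synth' must be given", call. = FALSE)
  }
  structure(list(out_dir = out_dir, counts = counts, synth = synth,
                 filter = filter, cluster = cluster, fdr = fdr,
                 null_n_loci = as.integer(null_n_loci), geo = geo,
                 selection = selection, annotation = annotation,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return a `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  do.call(run_config, yaml::read_yaml(path))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full psADE pipeline
#'
#' @param config a [run_config()] (or path to a YAML file for it).
#' @return the manifest (named list of stage outputs), invisibly; also
#'   written as `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(config$out_dir, f)
  manifest <- list(package_version = as.character(utils::packageVersion("psade")),
                   seed = config$seed, fdr = config$fdr, outputs = list())
  note <- function(stage, path) {
    manifest$outputs[[stage]] <<- path
  }

  # --- input ---------------------------------------------------------
  truth <- NULL
  if (!is.null(config$synth)) {
    scfg <- do.call(synth_config,
                    c(config$synth, list(seed = derive_seed(config$seed, 10L))))
    gen <- generate_table(scfg)
    tab <- gen$table
    truth <- gen$truth
    write_count_table(tab, outp("synthetic_counts.tsv"))
    write_truth_labels(truth, outp("synthetic_truth.tsv"))
    note("synth", outp("synthetic_counts.tsv"))
  } else {
    if (!file.exists(config$counts)) {
      stop("counts file not found: ", config$counts, call. = FALSE)
    }
    tab <- read_count_table(config$counts)
  }

  # --- filtering -----------------------------------------------------
  fcfg <- do.call(filter_config, config$filter)
  tab_f <- filter_loci(tab, fcfg, cluster = isTRUE(config$cluster))
  write_count_table(tab_f, outp("filtered_counts.tsv"))
  note("filter", outp("filtered_counts.tsv"))

  # --- population-genetic summaries ---------------------------------
  fs <- fst_summary(tab_f)
  .write_tsv(data.frame(locus_id = names(fs$fst), fst = fs$fst, lk = fs$lk,
                        stringsAsFactors = FALSE), outp("fst.tsv"))
  pw <- as.data.frame(fs$pairwise)
  pw <- cbind(population_id = rownames(fs$pairwise), pw)
  .write_tsv(pw, outp("pairwise_fst.tsv"))
  note("stats", outp("fst.tsv"))
  if (!is.null(config$geo)) {
    meta <- read_population_meta(config$geo)
    meta <- meta[match(tab_f$population_ids, meta$population_id), ]
    gd <- geo_distance_matrix(meta)
    mt <- mantel_test(fs$pairwise, gd, n_perm = 9999L,
                      seed = derive_seed(config$seed, 11L))
    jsonlite::write_json(mt, outp("mantel.json"), auto_unbox = TRUE, digits = NA)
    note("mantel", outp("mantel.json"))
  }

  # --- psADE detection ----------------------------------------------
  calls <- detect_psade(tab_f, config$fdr)
  .write_tsv(as.data.frame(calls), outp("calls.tsv"))
  note("detect", outp("calls.tsv"))
  tested <- attr(calls, "tested")

  # --- null-model noise calibration ---------------------------------
  if (config$null_n_loci > 0L) {
    pars <- lapply(tab_f$population_ids, function(p) learn_params(tab_f, p))
    reg <- fit_theta_mu(vapply(pars, `[[`, numeric(1), "mu"),
                        vapply(pars, `[[`, numeric(1), "theta"))
    rows <- lapply(seq_along(pars), function(i) {
      p <- pars[[i]]
      nr <- null_fdr_run(p, reg, config$null_n_loci, config$fdr,
                         seed = derive_seed(config$seed, 20L + i))
      obs_sig <- sum(calls$called[calls$population_id == p$population_id])
      data.frame(population_id = p$population_id, mu = p$mu, theta = p$theta,
                 alpha = p$alpha, beta = p$beta, gamma_shape = p$gamma_shape,
                 gamma_rate = p$gamma_rate, null_tested = nr$tested,
                 null_significant = nr$significant,
                 observed_tested = unname(tested[p$population_id]),
                 observed_significant = obs_sig,
                 true_positive_proportion = if (obs_sig > 0)
                   true_positive_proportion(tested[p$population_id], obs_sig,
                                            nr$tested, nr$significant)
                 else NA_real_,
                 stringsAsFactors = FALSE)
    })
    .write_tsv(do.call(rbind, rows), outp("null_sim.tsv"))
    note("simulate-null", outp("null_sim.tsv"))
  }

  # --- shared psADE vs differentiation ------------------------------
  sets <- psade_call_sets(calls)
  baf <- freq_matrix(tab_f)$baf
  if (length(unique(unlist(sets))) > 0L) {
    cr <- crossing_records(sets, baf)
    .write_tsv(cr, outp("crossings.tsv"))
    note("shared", outp("crossings.tsv"))
    if (nrow(cr) >= 4L && all(cr$shared_count > 0)) {
      fit <- tryCatch(fit_exp_decay(cr$median_fst, cr$shared_count),
                      error = function(e) NULL)
      if (!is.null(fit)) {
        jsonlite::write_json(fit[c("a", "b", "c", "pearson_r", "p")],
                             outp("decay_fit.json"), auto_unbox = TRUE,
                             digits = NA)
        note("decay-fit", outp("decay_fit.json"))
      }
    }
  }

  # --- selection overlap --------------------------------------------
  sel <- NULL
  if (!is.null(config$selection)) {
    sel <- read_selection_calls(config$selection)
  } else if (!is.null(truth)) {
    sel <- selection_calls(rownames(truth$freqs),
                           rownames(truth$freqs)[truth$is_selected])
  }
  if (!is.null(sel)) {
    rows <- lapply(names(sets), function(p) {
      ids <- calls$locus_id[calls$population_id == p]
      uni <- selection_calls(intersect(sel$universe, ids),
                             intersect(sel$selected, ids))
      if (!length(uni$universe)) return(NULL)
      ht <- suppressWarnings(hypergeom_overlap_test(
        intersect(sets[[p]], uni$universe), uni))
      data.frame(population_id = p, q = ht$q, m = ht$m, n = ht$n, k = ht$k,
                 p_value = ht$p, stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) {
      .write_tsv(do.call(rbind, rows), outp("selection_overlap.tsv"))
      note("intersect", outp("selection_overlap.tsv"))
    }
  }

  # --- annotation enrichment ----------------------------------------
  if (!is.null(config$annotation)) {
    ann <- utils::read.delim(config$annotation, comment.char = "#",
                             stringsAsFactors = FALSE)
    cand <- unique(calls$locus_id[calls$called])
    bg <- unique(calls$locus_id)
    enr <- enrichment_test(cand, bg, ann)
    .write_tsv(enr, outp("enrichment.tsv"))
    note("enrich", outp("enrichment.tsv"))
  }

  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
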