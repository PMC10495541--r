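#' Run the full analysis pipeline for one setting
#'
#' End-to-end orchestration: sample intersection, expression presence
#' filter (transcripts and genes), miRNA variance or top-k filter, site
#' categorization, pair-universe construction, alternative-splicing and
#' negative-correlation filters, one shared train/test split, nested
#' model fits with the RMSE gate, subsampled significance-ratio
#' distributions with real and permuted binding labels, and the
#' Mann-Whitney comparison of the two. All randomness derives from
#' `cfg$random_seed`; two runs with identical inputs and config are
#' identical.
#'
#' @param cfg A [pipeline_config()].
#' @param mirna_expr,transcript_expr,gene_expr [expression_matrix()]
#'   objects (log2 scale).
#' @param sites Site table from [read_site_predictions()].
#' @param annotation Annotation from [read_transcript_annotation()].
#' @param setting `"ALLT"`, `"TNBN"` or `"TBN"`.
#' @param covariate_mode If `TRUE` (TNBN only), each pair's model gains
#'   the most-correlated miRNA with a non-coding site on the gene as an
#'   extra covariate in both the full and the reduced model.
#' @param out_dir Optional directory: when given, per-pair results,
#'   ratio samples, the comparison summary, stage counts and the
#'   resolved configuration are written there as TSV/YAML.
#' @return List of class `"splicemir_run"`: `results`, `skipped`,
#'   `ratios` (real + randomized, stacked), `comparison`
#'   (a [compare_ratio_distributions()] result, or `NULL` when
#'   degenerate), `stage_counts`, `split`, `config`, `setting`,
#'   `degenerate`.
#' @export
run_pipeline <- function(cfg, mirna_expr, transcript_expr, gene_expr,
                         sites, annotation,
                         setting = c("ALLT", "TNBN", "TBN"),
                         covariate_mode = FALSE, out_dir = NULL) {
  setting <- match.arg(setting)
  stopifnot(inherits(cfg, "pipeline_config"),
            inherits(mirna_expr, "expression_matrix"),
            inherits(transcript_expr, "expression_matrix"),
            inherits(gene_expr, "expression_matrix"))
  if (covariate_mode && setting != "TNBN") {
    stop("covariate_mode is only valid with setting TNBN ",
         "(it models a correlated miRNA acting through non-coding sites)")
  }
  stage <- list()
  note <- function(name, n_in, n_out) {
    stage[[length(stage) + 1L]] <<- data.frame(
      stage = name, items_in = n_in, items_out = n_out,
      stringsAsFactors = FALSE)
  }

  common <- Reduce(intersect, list(sample_ids(mirna_expr),
                                   sample_ids(transcript_expr),
                                   sample_ids(gene_expr)))
  if (!length(common)) stop("no samples shared by the three expression matrices")
  note("sample_intersection",
       max(nrow(mirna_expr$values), nrow(transcript_expr$values),
           nrow(gene_expr$values)), length(common))
  mirna_expr <- em_subset(mirna_expr, samples = common)
  transcript_expr <- em_subset(transcript_expr, samples = common)
  gene_expr <- em_subset(gene_expr, samples = common)

  tx_keep <- presence_filter(transcript_expr, cfg)
  note("presence_filter_transcripts", ncol(transcript_expr$values),
       length(tx_keep))
  gene_keep <- presence_filter(gene_expr, cfg)
  note("presence_filter_genes", ncol(gene_expr$values), length(gene_keep))
  if (!is.null(cfg$top_k_mirnas)) {
    mir_keep <- top_k_expression_filter(mirna_expr,
                                        min(cfg$top_k_mirnas,
                                            ncol(mirna_expr$values)))
    note("top_k_mirna_filter", ncol(mirna_expr$values), length(mir_keep))
  } else {
    mir_keep <- variance_filter(mirna_expr, cfg)
    note("variance_filter_mirnas", ncol(mirna_expr$values), length(mir_keep))
  }
  transcript_expr <- em_subset(transcript_expr, features = tx_keep)
  gene_expr <- em_subset(gene_expr, features = gene_keep)
  mirna_expr <- em_subset(mirna_expr, features = mir_keep)

  use_sites <- sites[sites$mirna_id %in% mir_keep &
                       sites$transcript_id %in% annotation$transcript_id, ,
                     drop = FALSE]
  categories <- categorize_sites(use_sites, annotation, cfg)
  note("site_categorization", nrow(use_sites), nrow(categories))

  universes <- build_pair_universe(categories, annotation, setting, cfg)
  n_u0 <- length(universes)
  # drop transcripts lost to the presence filter, then re-validate nesting
  universes <- lapply(universes, function(u) {
    full <- intersect(u$full, tx_keep)
    reduced <- intersect(u$reduced, tx_keep)
    if (length(reduced) >= 1L && length(full) > length(reduced) &&
          u$gene_id %in% gene_keep) {
      pair_universe(u$mirna_id, u$gene_id, u$setting, full, reduced)
    } else NULL
  })
  universes <- universes[!vapply(universes, is.null, logical(1))]
  note("pair_universe", n_u0, length(universes))

  n_as0 <- length(universes)
  universes <- alternative_splicing_filter(universes)
  note("alternative_splicing_filter", n_as0, length(universes))

  corr_audit <- data.frame(mirna = character(0), gene = character(0),
                           r = numeric(0), keep = logical(0))
  if (length(universes)) {
    corr <- lapply(universes, function(u) {
      correlation_filter(mirna_expr$values[, u$mirna_id],
                         gene_expr$values[, u$gene_id])
    })
    corr_audit <- data.frame(
      mirna = vapply(universes, `[[`, character(1), "mirna_id"),
      gene = vapply(universes, `[[`, character(1), "gene_id"),
      r = vapply(corr, `[[`, numeric(1), "r"),
      keep = vapply(corr, `[[`, logical(1), "keep"),
      stringsAsFactors = FALSE)
    universes <- universes[corr_audit$keep]
  }
  note("correlation_filter", nrow(corr_audit), length(universes))

  if (!length(universes)) {
    sm_log("zero pairs after filtering; run marked degenerate")
    run <- structure(list(
      results = data.frame(), skipped = data.frame(),
      ratios = data.frame(), comparison = NULL,
      stage_counts = do.call(rbind, stage),
      correlation_audit = corr_audit,
      split = NULL, config = cfg, setting = setting,
      covariate_mode = covariate_mode, degenerate = TRUE),
      class = "splicemir_run")
    if (!is.null(out_dir)) write_run_outputs(run, out_dir)
    return(run)
  }

  split <- split_samples(common, cfg)

  covariates <- NULL
  if (covariate_mode) {
    covariates <- lapply(universes, function(u) {
      select_covariate_mirna(u, sites, annotation, mirna_expr, cfg)
    })
  }

  fits <- fit_all_pairs(universes, transcript_expr, mirna_expr, split, cfg,
                        covariates = covariates)
  note("model_fitting", length(universes), nrow(fits$results))
  note("rmse_gate", nrow(fits$results),
       sum(fits$results$passed_rmse_gate %||% logical(0)))

  degenerate <- nrow(fits$results) == 0L
  ratios <- data.frame()
  comparison <- NULL
  if (!degenerate) {
    real <- subsample_significance_ratio(fits$results, cfg)
    rand <- randomized_significance_ratio(fits, cfg)
    ratios <- rbind(real, rand)
    comparison <- compare_ratio_distributions(real, rand,
                                              alternative = cfg$mw_alternative)
  }
  run <- structure(list(
    results = fits$results, skipped = fits$skipped, ratios = ratios,
    comparison = comparison, stage_counts = do.call(rbind, stage),
    correlation_audit = corr_audit, split = split, config = cfg,
    setting = setting, covariate_mode = covariate_mode,
    degenerate = degenerate),
    class = "splicemir_run")
  if (!is.null(out_dir)) write_run_outputs(run, out_dir)
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stage count report
#'
#' Table of item counts entering and leaving each pipeline stage of a
#' completed run, mirroring the intermediate pair-count bookkeeping of
#' the analysis protocol.
#'
#' @param run A `"splicemir_run"`.
#' @return Data.frame with columns `stage`, `items_in`, `items_out`.
#' @export
stage_count_report <- function(run) {
  stopifnot(inherits(run, "splicemir_run"))
  run$stage_counts
}

#' Write run outputs to a directory
#'
#' Per-pair results (TSV), skipped pairs, ratio samples, the comparison
#' summary, stage counts and the resolved configuration (YAML).
#'
#' @param run A `"splicemir_run"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_results_table(run$results, file.path(dir, "pair_results.tsv"))
  data.table::fwrite(run$skipped, file.path(dir, "skipped_pairs.tsv"),
                     sep = "\t")
  data.table::fwrite(run$ratios, file.path(dir, "ratio_samples.tsv"),
                     sep = "\t")
  data.table::fwrite(run$stage_counts, file.path(dir, "stage_counts.tsv"),
                     sep = "\t")
  summ <- if (is.null(run$comparison)) {
    data.frame(setting = run$setting, degenerate = TRUE,
               mean_ratio_real = NA_real_, mean_ratio_random = NA_real_,
               dist = NA_real_, u_statistic = NA_real_, p_value = NA_real_)
  } else {
    data.frame(setting = run$setting, degenerate = FALSE,
               mean_ratio_real = run$comparison$mean_ratio_real,
               mean_ratio_random = run$comparison$mean_ratio_random,
               dist = run$comparison$dist,
               u_statistic = run$comparison$u_statistic,
               p_value = run$comparison$p_value)
  }
  data.table::fwrite(summ, file.path(dir, "summary.tsv"), sep = "\t")
  cfg <- run$config
  cfg_list <- unclass(cfg)
  cfg_list <- cfg_list[!vapply(cfg_list, is.null, logical(1))]
  yaml::write_yaml(cfg_list, file.path(dir, "config_resolved.yaml"))
  invisible(dir)
}

#' @export
print.splicemir_run <- function(x, ...) {
  cat(sprintf("splicemir run [%s]%s: %d pairs fitted, %d skipped\n",
              x$setting, if (x$covariate_mode) " +covariate" else "",
              nrow(x$results), nrow(x$skipped)))
  if (x$degenerate) {
    cat("  degenerate run: no analyzable pairs\n")
  } else {
    print(x$comparison)
  }
  invisible(x)
}
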