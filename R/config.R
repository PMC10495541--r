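#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis in one validated object.
#' Defaults follow the published analysis protocol: binding-probability
#' cutoffs 0.5/0.8, miRNA variance cutoff 0.2, absent-fraction cutoff 0.25,
#' 80/20 train/test split, test RMSE gate 0.7, BH FDR level 0.05, and
#' 1000 subsamples of 10000 miRNA-gene pairs.
#'
#' @param bind_prob_high Sites above this binding probability define
#'   "binding" transcripts (default 0.80).
#' @param bind_prob_low Sites above this probability disqualify a transcript
#'   from being "non-binding" (default 0.50). Transcripts whose sites all
#'   fall between the two cutoffs are discarded as noise.
#' @param min_mirna_variance miRNAs with sample variance (denominator n-1)
#'   below this are removed (default 0.2).
#' @param max_absent_fraction Transcripts/genes absent in at least this
#'   fraction of samples are removed (default 0.25).
#' @param top_k_mirnas If not `NULL`, keep the k most highly expressed
#'   miRNAs (by mean) instead of the variance filter (the small-RNA-seq
#'   protocol used 100).
#' @param train_fraction Fraction of samples used for training (default 0.8).
#' @param rmse_threshold Test-set RMSE gate: both the full and the reduced
#'   model must score below this (default 0.7, log2 units).
#' @param fdr_alpha Benjamini-Hochberg significance level (default 0.05).
#' @param subsample_size Pairs drawn per subsampling iteration (default 10000).
#' @param subsample_iterations Number of subsampling iterations (default 1000).
#' @param random_seed Integer seed governing the sample split, subsampling
#'   and label permutation.
#' @param bh_scope `"per_iteration"` (default) applies the BH correction
#'   within each subsample; `"global"` reuses the one correction computed
#'   over all gate-passing pairs.
#' @param covariate_correlation `"signed"` (default) picks the covariate
#'   miRNA with the highest Pearson correlation; `"absolute"` uses |r|.
#' @param mw_alternative Alternative hypothesis for the Mann-Whitney
#'   comparison of ratio distributions (default `"two.sided"`).
#' @param expression_floor Log2 value representing "not expressed"
#'   (default `log2(0.001)`, the pseudocount floor of log2(tpm + 0.001)).
#' @return An object of class `"pipeline_config"` (a validated list).
#' @export
#' @examples
#' cfg <- pipeline_config(subsample_size = 100, subsample_iterations = 10)
#' cfg$rmse_threshold
pipeline_config <- function(bind_prob_high = 0.80,
                            bind_prob_low = 0.50,
                            min_mirna_variance = 0.2,
                            max_absent_fraction = 0.25,
                            top_k_mirnas = NULL,
                            train_fraction = 0.8,
                            rmse_threshold = 0.7,
                            fdr_alpha = 0.05,
                            subsample_size = 10000L,
                            subsample_iterations = 1000L,
                            random_seed = 1L,
                            bh_scope = c("per_iteration", "global"),
                            covariate_correlation = c("signed", "absolute"),
                            mw_alternative = c("two.sided", "greater", "less"),
                            expression_floor = log2(0.001)) {
  bh_scope <- match.arg(bh_scope)
  covariate_correlation <- match.arg(covariate_correlation)
  mw_alternative <- match.arg(mw_alternative)
  stopifnot(
    is.numeric(bind_prob_low), is.numeric(bind_prob_high),
    length(bind_prob_low) == 1L, length(bind_prob_high) == 1L,
    bind_prob_low > 0, bind_prob_low < bind_prob_high, bind_prob_high <= 1,
    min_mirna_variance >= 0,
    max_absent_fraction >= 0, max_absent_fraction <= 1,
    train_fraction > 0, train_fraction < 1,
    rmse_threshold >= 0,
    fdr_alpha > 0, fdr_alpha < 1,
    subsample_size >= 1, subsample_iterations >= 1,
    is.numeric(random_seed), length(random_seed) == 1L, is.finite(random_seed)
  )
  if (!is.null(top_k_mirnas)) {
    stopifnot(is.numeric(top_k_mirnas), length(top_k_mirnas) == 1L,
              top_k_mirnas >= 1)
    top_k_mirnas <- as.integer(top_k_mirnas)
  }
  structure(list(
    bind_prob_high = bind_prob_high,
    bind_prob_low = bind_prob_low,
    min_mirna_variance = min_mirna_variance,
    max_absent_fraction = max_absent_fraction,
    top_k_mirnas = top_k_mirnas,
    train_fraction = train_fraction,
    rmse_threshold = rmse_threshold,
    fdr_alpha = fdr_alpha,
    subsample_size = as.integer(subsample_size),
    subsample_iterations = as.integer(subsample_iterations),
    random_seed = as.integer(random_seed),
    bh_scope = bh_scope,
    covariate_correlation = covariate_correlation,
    mw_alternative = mw_alternative,
    expression_floor = expression_floor
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat keys mirroring the arguments of [pipeline_config()]; keys absent
#' from the file fall back to the defaults. Unknown keys are an error so
#' that typos do not silently revert a threshold to its default.
#'
#' @param path Path to a YAML file.
#' @return A `"pipeline_config"` object.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("splicemir pipeline configuration\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm,
                if (is.null(val)) "NULL" else paste(format(val), collapse = " ")))
  }
  invisible(x)
}

# Lightweight logging used by the pipeline stages; silenced via
# options(splicemir.verbose = FALSE).
sm_log <- function(...) {
  if (isTRUE(getOption("splicemir.verbose", TRUE))) {
    message("[splicemir] ", sprintf(...))
  }
  invisible(NULL)
}
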