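#' Expression presence filter
#'
#' Keeps transcripts/genes that are expressed in more than
#' `1 - max_absent_fraction` of samples. "Expressed" means strictly above
#' the matrix floor plus a small tolerance (the log2(x + 0.001) transform
#' maps absent features to a constant floor). A feature absent in exactly
#' the threshold fraction of samples (e.g. 25%) is dropped.
#'
#' @param matrix An [expression_matrix()] of kind `"transcript"` or
#'   `"gene"`.
#' @param cfg A [pipeline_config()].
#' @param tol Tolerance above the floor still counting as absent
#'   (default 1e-9).
#' @return Character vector of feature ids kept.
#' @export
presence_filter <- function(matrix, cfg = pipeline_config(), tol = 1e-9) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (!matrix$kind %in% c("transcript", "gene")) {
    stop("presence_filter applies to transcript or gene matrices, got ",
         matrix$kind)
  }
  absent_frac <- colMeans(matrix$values <= matrix$floor + tol)
  kept <- feature_ids(matrix)[absent_frac < cfg$max_absent_fraction]
  sm_log("presence filter [%s]: %d of %d features kept",
         matrix$kind, length(kept), ncol(matrix$values))
  kept
}

#' miRNA variance filter
#'
#' Keeps miRNAs whose sample variance (denominator n - 1) is at least
#' `min_mirna_variance`; low-variance miRNAs carry no signal for the
#' regression and invite overfitting. Variance exactly at the cutoff is
#' kept.
#'
#' @param matrix An [expression_matrix()] of kind `"mirna"`.
#' @param cfg A [pipeline_config()].
#' @return Character vector of miRNA ids kept.
#' @export
variance_filter <- function(matrix, cfg = pipeline_config()) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (matrix$kind != "mirna") {
    stop("variance_filter applies to the miRNA matrix, got ", matrix$kind)
  }
  if (nrow(matrix$values) < 2L) stop("variance filter needs at least 2 samples")
  v <- apply(matrix$values, 2L, stats::var)
  kept <- feature_ids(matrix)[v >= cfg$min_mirna_variance]
  sm_log("variance filter: %d of %d miRNAs kept", length(kept),
         ncol(matrix$values))
  kept
}

#' Top-k expression filter for miRNAs
#'
#' Keeps the k miRNAs with the highest mean expression across samples
#' (the small-RNA-seq protocol retains the 100 most highly expressed).
#' Ties at the k-th rank are broken by identifier order, so the result
#' is deterministic.
#'
#' @param matrix An [expression_matrix()] of kind `"mirna"`.
#' @param k Number of miRNAs to keep (1 <= k <= number of miRNAs).
#' @return Character vector of the k miRNA ids kept.
#' @export
top_k_expression_filter <- function(matrix, k) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (matrix$kind != "mirna") {
    stop("top_k_expression_filter applies to the miRNA matrix, got ",
         matrix$kind)
  }
  n <- ncol(matrix$values)
  if (!is.numeric(k) || length(k) != 1L || k <= 0) stop("k must be positive")
  if (k > n) stop("k (", k, ") exceeds the number of miRNAs (", n, ")")
  means <- colMeans(matrix$values)
  ids <- feature_ids(matrix)
  ord <- order(-means, ids)
  kept <- ids[ord[seq_len(k)]]
  sm_log("top-k filter: kept %d of %d miRNAs", length(kept), n)
  kept
}

#' Alternative-splicing filter
#'
#' A miRNA-gene pair is analyzable only when the gene is alternatively
#' spliced with respect to the investigated region: at least one
#' transcript carries a high-confidence site there (`full` minus
#' `reduced`) and at least one other transcript carries none (`reduced`).
#' Pair universes emitted by [build_pair_universe()] already satisfy
#' this; the filter re-checks after any subsequent pruning (e.g. the
#' expression presence filter removing transcripts).
#'
#' @param universes List of pair universes (one setting).
#' @return The sublist of universes passing the filter.
#' @export
alternative_splicing_filter <- function(universes) {
  keep <- vapply(universes, function(u) {
    length(setdiff(u$full, u$reduced)) >= 1L && length(u$reduced) >= 1L
  }, logical(1))
  sm_log("alternative splicing filter: %d of %d pairs kept",
         sum(keep), length(universes))
  universes[keep]
}

#' Negative-correlation filter for one miRNA-gene pair
#'
#' miRNAs predominantly repress their targets, so only pairs with a
#' strictly negative Pearson correlation between miRNA and gene
#' expression (computed over all samples, before the train/test split)
#' are retained. A correlation of exactly zero is removed. Constant
#' vectors leave r undefined; the pair is removed with the reason
#' recorded.
#'
#' @param mirna_expr,gene_expr Numeric vectors over the same samples in
#'   the same order (length >= 3).
#' @return List with `r` (Pearson correlation or `NA`), `keep` (logical)
#'   and `reason` (character, `NA` when kept).
#' @export
correlation_filter <- function(mirna_expr, gene_expr) {
  if (length(mirna_expr) != length(gene_expr)) {
    stop("vectors differ in length")
  }
  if (length(mirna_expr) < 3L) stop("correlation filter needs >= 3 samples")
  if (stats::sd(mirna_expr) == 0 || stats::sd(gene_expr) == 0) {
    return(list(r = NA_real_, keep = FALSE,
                reason = "constant expression vector; correlation undefined"))
  }
  r <- stats::cor(mirna_expr, gene_expr, method = "pearson")
  list(r = r, keep = r < 0,
       reason = if (r < 0) NA_character_ else "non-negative correlation")
}
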