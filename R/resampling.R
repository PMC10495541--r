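#' Subsampled significance-ratio distribution (real labels)
#'
#' Estimates the sampling distribution of the significant-model ratio:
#' per iteration, draws `subsample_size` pairs uniformly without
#' replacement (capped at the number of available pairs, with a logged
#' warning), keeps those passing the RMSE gate, applies the BH
#' correction within the subsample (default; a global correction is
#' available via `cfg$bh_scope`), and records the fraction of
#' gate-passing pairs that are significant. Iteration i uses seed
#' `random_seed + i`, so iterations are reproducible and independent of
#' execution order.
#'
#' @param results Per-pair results data.frame from [fit_all_pairs()]
#'   (columns `p`, `passed_rmse_gate`, and `p_adj` for global scope).
#' @param cfg A [pipeline_config()].
#' @return Data.frame with columns `iteration`, `ratio`, `randomized`
#'   (all `FALSE`), `n_pairs_tested` (gate-passing pairs in the
#'   subsample).
#' @export
subsample_significance_ratio <- function(results, cfg = pipeline_config()) {
  results <- as.data.frame(results)
  n <- nrow(results)
  if (n == 0L) stop("empty results: nothing to subsample")
  m <- cfg$subsample_size
  if (m > n) {
    sm_log("subsample_size %d exceeds the %d available pairs; sampling all",
           m, n)
    m <- n
  }
  iters <- cfg$subsample_iterations
  ratio <- numeric(iters)
  tested <- integer(iters)
  for (i in seq_len(iters)) {
    set.seed(cfg$random_seed + i)
    idx <- sample.int(n, m)
    sub <- results[idx, , drop = FALSE]
    gated <- sub[sub$passed_rmse_gate & !is.na(sub$p), , drop = FALSE]
    tested[i] <- nrow(gated)
    if (nrow(gated) == 0L) {
      ratio[i] <- 0
    } else if (cfg$bh_scope == "global") {
      ratio[i] <- mean(gated$p_adj < cfg$fdr_alpha)
    } else {
      bh <- benjamini_hochberg(gated$p, cfg$fdr_alpha)
      ratio[i] <- mean(bh$significant)
    }
  }
  data.frame(iteration = seq_len(iters), ratio = ratio,
             randomized = FALSE, n_pairs_tested = tested)
}

#' Shuffle binding labels within a gene
#'
#' The permutation null: reassigns which transcripts of the pair count
#' as "binding" by drawing a uniform random subset of the full set of
#' the original binding size. The full set and the binding /
#' non-binding counts are preserved exactly; only the membership of the
#' reduced (escape) set changes.
#'
#' @param pair A [pair_universe()].
#' @param seed Optional integer seed; `NULL` uses the current RNG
#'   stream.
#' @return A new [pair_universe()] with permuted `reduced` membership.
#' @export
randomize_binding_labels <- function(pair, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- length(pair$full) - length(pair$reduced)
  binding_new <- sample(pair$full, b)
  reduced_new <- setdiff(pair$full, binding_new)
  pair_universe(pair$mirna_id, pair$gene_id, pair$setting,
                full = pair$full, reduced = reduced_new)
}

#' Subsampled significance-ratio distribution under the label-shuffle null
#'
#' Repeats the subsampling of [subsample_significance_ratio()] but
#' shuffles the transcript binding labels within each gene before
#' testing. The full model is invariant under the shuffle (its
#' membership never changes), so cached full fits are reused; only the
#' reduced models are retrained, the RMSE gate is re-evaluated with the
#' retrained reduced RMSE and the original full RMSE, and the LRT and
#' BH correction are recomputed. Iteration i uses seed
#' `random_seed + subsample_iterations + i`, a stream disjoint from the
#' real-label subsampling.
#'
#' @param fits A `"pair_fits"` bundle from [fit_all_pairs()].
#' @param cfg A [pipeline_config()].
#' @return Data.frame with columns `iteration`, `ratio`, `randomized`
#'   (all `TRUE`), `n_pairs_tested`.
#' @export
randomized_significance_ratio <- function(fits, cfg = pipeline_config()) {
  stopifnot(inherits(fits, "pair_fits"))
  n <- nrow(fits$results)
  if (n == 0L) stop("empty results: nothing to randomize")
  m <- min(cfg$subsample_size, n)
  if (cfg$subsample_size > n) {
    sm_log("subsample_size %d exceeds the %d available pairs; sampling all",
           cfg$subsample_size, n)
  }
  iters <- cfg$subsample_iterations
  thr <- cfg$rmse_threshold
  ratio <- numeric(iters)
  tested <- integer(iters)
  for (i in seq_len(iters)) {
    set.seed(cfg$random_seed + cfg$subsample_iterations + i)
    idx <- sample.int(n, m)
    pv <- rep(NA_real_, m)
    gate <- logical(m)
    for (j in seq_len(m)) {
      cc <- fits$fits[[idx[j]]]
      b <- length(cc$full_ids) - length(cc$reduced_ids)
      binding_new <- sample(cc$full_ids, b)
      reduced_new <- setdiff(cc$full_ids, binding_new)
      cols <- c(reduced_new, cc$covariate)
      Xr <- cbind(1, cc$X_train[, cols, drop = FALSE])
      ft <- stats::.lm.fit(Xr, cc$y_train)
      rss_r <- sum(ft$residuals^2)
      pred <- drop(cbind(1, cc$X_test[, cols, drop = FALSE]) %*% ft$coefficients)
      rmse_r <- sqrt(mean((cc$y_test - pred)^2))
      gate[j] <- cc$rmse_full < thr && rmse_r < thr
      if (gate[j] && cc$rss_full > 0) {
        lambda <- max(cc$n_train * log(rss_r / cc$rss_full), 0)
        pv[j] <- stats::pchisq(lambda, df = b, lower.tail = FALSE)
      }
    }
    ok <- gate & !is.na(pv)
    tested[i] <- sum(ok)
    if (!any(ok)) {
      ratio[i] <- 0
    } else {
      bh <- benjamini_hochberg(pv[ok], cfg$fdr_alpha)
      ratio[i] <- mean(bh$significant)
    }
  }
  data.frame(iteration = seq_len(iters), ratio = ratio,
             randomized = TRUE, n_pairs_tested = tested)
}

#' Compare real and randomized ratio distributions
#'
#' Mann-Whitney U comparison of the significance-ratio samples obtained
#' with real vs. permuted binding labels, together with the difference
#' of the two means (`dist`). Small samples are compared by exact
#' enumeration of group assignments (which handles the heavy ties of
#' ratio data); larger samples use the normal approximation with tie
#' correction. When every pooled value is identical the comparison is
#' degenerate: U = nm/2 and p = 1.
#'
#' @param real,random Data.frames from [subsample_significance_ratio()]
#'   and [randomized_significance_ratio()]; the `randomized` flags must
#'   be homogeneous and correct.
#' @param alternative `"two.sided"` (default), `"greater"` (real > null)
#'   or `"less"`.
#' @return List of class `"distribution_comparison"`:
#'   `mean_ratio_real`, `mean_ratio_random`, `dist`
#'   (= real - random), `u_statistic`, `p_value`, `n_real`, `n_random`,
#'   `method`.
#' @export
compare_ratio_distributions <- function(real, random,
                                        alternative = c("two.sided",
                                                        "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!nrow(real) || !nrow(random)) stop("both ratio samples must be non-empty")
  if (any(real$randomized)) stop("real sample contains randomized entries")
  if (!all(random$randomized)) stop("random sample contains non-randomized entries")
  x <- real$ratio; y <- random$ratio
  nx <- length(x); ny <- length(y)
  mean_x <- mean(x); mean_y <- mean(y)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    comp <- list(u = nx * ny / 2, p = 1, method = "degenerate (all values tied)")
  } else if (choose(nx + ny, min(nx, ny)) <= 5e5) {
    comp <- mw_exact(x, y, alternative)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                              exact = FALSE, correct = TRUE))
    comp <- list(u = unname(wt$statistic), p = wt$p.value,
                 method = "normal approximation with tie correction")
  }
  structure(list(mean_ratio_real = mean_x, mean_ratio_random = mean_y,
                 dist = mean_x - mean_y, u_statistic = comp$u,
                 p_value = comp$p, n_real = nx, n_random = ny,
                 alternative = alternative, method = comp$method),
            class = "distribution_comparison")
}

# Exact Mann-Whitney by enumeration of all C(nx+ny, nx) assignments of
# the pooled values to the first group; correct under ties.
mw_exact <- function(x, y, alternative) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  u_all <- apply(combos, 2L, function(ix) sum(rk[ix])) - nx * (nx + 1) / 2
  eps <- 1e-9
  p <- switch(alternative,
    two.sided = mean(abs(u_all - nx * ny / 2) >= abs(u_obs - nx * ny / 2) - eps),
    greater = mean(u_all >= u_obs - eps),
    less = mean(u_all <= u_obs + eps)
  )
  list(u = u_obs, p = min(p, 1), method = "exact enumeration")
}

#' @export
print.distribution_comparison <- function(x, ...) {
  cat(sprintf(paste0(
    "ratio distribution comparison (%s)\n",
    "  mean ratio, real labels:       %.4f (n = %d)\n",
    "  mean ratio, permuted labels:   %.4f (n = %d)\n",
    "  dist (real - permuted):        %.4f\n",
    "  Mann-Whitney U = %.1f, %s p = %.3g\n"),
    x$method, x$mean_ratio_real, x$n_real, x$mean_ratio_random, x$n_random,
    x$dist, x$u_statistic, x$alternative, x$p_value))
  invisible(x)
}
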