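#' Split samples into training and test sets
#'
#' One shared split per dataset, used by every miRNA-gene pair, drawn
#' deterministically from the configured seed. The training set holds
#' `round(train_fraction * n)` samples.
#'
#' @param sample_ids Character vector of sample ids (>= 10).
#' @param cfg A [pipeline_config()] supplying `train_fraction` and
#'   `random_seed`.
#' @return List of class `"sample_split"` with `train_ids`, `test_ids`
#'   and `seed`.
#' @export
split_samples <- function(sample_ids, cfg = pipeline_config()) {
  n <- length(sample_ids)
  if (n < 10L) stop("need at least 10 samples to split, got ", n)
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  n_train <- round(cfg$train_fraction * n)
  if (n_train < 1L || n_train >= n) stop("degenerate split: n_train = ", n_train)
  set.seed(cfg$random_seed)
  idx <- sample.int(n, n_train)
  structure(list(train_ids = sample_ids[sort(idx)],
                 test_ids = sample_ids[sort(setdiff(seq_len(n), idx))],
                 seed = cfg$random_seed),
            class = "sample_split")
}

#' Ordinary least squares fit with an implicit intercept
#'
#' Fits `response ~ 1 + predictors` by least squares. On rank-deficient
#' designs (e.g. duplicated predictor columns) the minimum-norm solution
#' is taken via the pseudoinverse and `rank_deficient` is set; fitted
#' values equal the projection either way.
#'
#' @param predictors Numeric matrix (samples x predictors) with column
#'   names, or `NULL` for an intercept-only fit.
#' @param response Numeric vector, one value per training sample.
#' @return List of class `"ols_fit"`: `coefficients` (named, intercept
#'   first), `rss`, `n_train`, `n_params`, `adj_r2`, `rank_deficient`,
#'   `predictor_ids`.
#' @export
fit_ols <- function(predictors, response) {
  n <- length(response)
  if (n == 0L) stop("zero training samples")
  if (is.null(predictors)) {
    predictors <- matrix(numeric(0), nrow = n, ncol = 0)
  }
  if (!is.matrix(predictors)) predictors <- as.matrix(predictors)
  if (nrow(predictors) != n) stop("predictor rows must match response length")
  if (ncol(predictors) > 0L && is.null(colnames(predictors))) {
    stop("predictor columns must be named")
  }
  X <- cbind(`(Intercept)` = rep(1, n), predictors)
  qx <- qr(X)
  rank_deficient <- qx$rank < ncol(X)
  if (!rank_deficient) {
    coef <- qr.coef(qx, response)
    fitted <- drop(X %*% coef)
  } else {
    sv <- svd(X)
    tol <- max(dim(X)) * .Machine$double.eps * sv$d[1L]
    dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
    coef <- drop(sv$v %*% (dinv * crossprod(sv$u, response)))
    names(coef) <- colnames(X)
    fitted <- drop(X %*% coef)
  }
  rss <- sum((response - fitted)^2)
  n_params <- ncol(X)
  tss <- sum((response - mean(response))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  adj_r2 <- if (!is.na(r2) && n > n_params) {
    1 - (1 - r2) * (n - 1) / (n - n_params)
  } else NA_real_
  structure(list(coefficients = coef, rss = rss, n_train = n,
                 n_params = n_params, r2 = r2, adj_r2 = adj_r2,
                 rank_deficient = rank_deficient,
                 predictor_ids = colnames(predictors)),
            class = "ols_fit")
}

#' Root mean squared error of a fit on held-out samples
#'
#' @param fit An [fit_ols()] result.
#' @param predictors Numeric matrix over the evaluation samples; must
#'   contain the fit's predictor columns (matched by name).
#' @param response Numeric vector over the same samples (non-empty).
#' @return The RMSE (a scalar).
#' @export
rmse_on <- function(fit, predictors, response) {
  n <- length(response)
  if (n == 0L) stop("empty evaluation sample set")
  ids <- fit$predictor_ids
  if (length(ids)) {
    if (is.null(predictors) || !all(ids %in% colnames(predictors))) {
      stop("evaluation predictors lack column(s): ",
           paste(setdiff(ids, colnames(predictors)), collapse = ", "))
    }
    X <- cbind(1, as.matrix(predictors)[, ids, drop = FALSE])
  } else {
    X <- matrix(1, nrow = n, ncol = 1)
  }
  pred <- drop(X %*% fit$coefficients)
  sqrt(mean((response - pred)^2))
}

#' Likelihood-ratio test between nested OLS fits
#'
#' Gaussian-MLE form: the statistic is
#' `n * ln(RSS_reduced / RSS_full)` with `df` the difference in parameter
#' counts, referred to the upper tail of the chi-squared distribution.
#' Numerically negative statistics (RSS_reduced marginally below
#' RSS_full) are clipped at zero.
#'
#' @param full,reduced [fit_ols()] results over the same training
#'   samples; the reduced predictors must be a subset of the full ones.
#' @return List with `lrt_stat`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "ols_fit"), inherits(reduced, "ols_fit"))
  if (full$n_train != reduced$n_train) {
    stop("fits use different numbers of training samples")
  }
  if (!all(reduced$predictor_ids %in% full$predictor_ids) ||
        reduced$n_params >= full$n_params) {
    stop("models are not nested (reduced must use a strict subset of predictors)")
  }
  if (!(full$rss > 0)) stop("full-model RSS must be positive for the LRT")
  lambda <- full$n_train * log(reduced$rss / full$rss)
  lambda <- max(lambda, 0)
  df <- full$n_params - reduced$n_params
  list(lrt_stat = lambda, df = df,
       p = stats::pchisq(lambda, df = df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment with significance flags
#'
#' Step-up FDR adjustment of a p-value vector with flags at the given
#' level. The adjustment is the standard one (delegated to
#' [stats::p.adjust()]).
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param alpha Significance level for the flags (default 0.05).
#' @return List with `p_adj` and logical `significant`
#'   (`p_adj < alpha`).
#' @export
benjamini_hochberg <- function(pvals, alpha = 0.05) {
  if (length(pvals) && (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(pvals, method = "BH")
  list(p_adj = adj, significant = adj < alpha)
}

#' Cohen's f-squared for nested models
#'
#' Effect size of the full over the reduced model,
#' `f2 = (adjR2_full - adjR2_reduced) / (1 - adjR2_full)`, with the
#' conventional bins: small >= 0.02, medium >= 0.15, large >= 0.35.
#' Negative values (the adjustment can invert the order) are reported
#' as-is and binned `"none"`.
#'
#' @param adj_r2_full,adj_r2_reduced Adjusted R-squared of the two fits;
#'   `adj_r2_full` must be < 1.
#' @return List with `f2` and `bin`
#'   (`"none"`, `"small"`, `"medium"`, `"large"`).
#' @export
cohens_f2 <- function(adj_r2_full, adj_r2_reduced) {
  if (is.na(adj_r2_full) || is.na(adj_r2_reduced)) {
    return(list(f2 = NA_real_, bin = NA_character_))
  }
  if (adj_r2_full >= 1) {
    warning("adjusted R-squared of the full model >= 1; f2 undefined")
    return(list(f2 = NA_real_, bin = NA_character_))
  }
  f2 <- (adj_r2_full - adj_r2_reduced) / (1 - adj_r2_full)
  bin <- if (f2 >= 0.35) "large" else if (f2 >= 0.15) "medium"
         else if (f2 >= 0.02) "small" else "none"
  list(f2 = f2, bin = bin)
}

#' Select the covariate miRNA for a TNBN pair
#'
#' For a pair (M1, G), finds the miRNA (other than M1) that is predicted
#' to bind the non-coding region of any transcript of G with probability
#' above the low cutoff and whose expression is most correlated with
#' M1's. Used to absorb regulation acting through non-coding sites of a
#' correlated miRNA. Ties are broken by identifier order.
#'
#' @param pair A [pair_universe()] with setting `"TNBN"`.
#' @param sites Full site table (all miRNAs).
#' @param annotation Annotation data.frame.
#' @param mirna_expr miRNA [expression_matrix()].
#' @param cfg A [pipeline_config()]; `covariate_correlation` chooses
#'   signed (default) or absolute correlation maximization.
#' @return A miRNA id, or `NULL` when no candidate exists.
#' @export
select_covariate_mirna <- function(pair, sites, annotation, mirna_expr,
                                   cfg = pipeline_config()) {
  if (!identical(pair$setting, "TNBN")) {
    stop("covariate selection applies to TNBN pairs only")
  }
  txs <- annotation[annotation$gene_id == pair$gene_id, , drop = FALSE]
  ss <- sites[sites$transcript_id %in% txs$transcript_id &
                sites$probability > cfg$bind_prob_low &
                sites$mirna_id != pair$mirna_id, , drop = FALSE]
  if (!nrow(ss)) return(NULL)
  lut <- txs[match(ss$transcript_id, txs$transcript_id), ]
  noncod <- ss$start < lut$cds_start | ss$end > lut$cds_end
  cand <- sort(unique(ss$mirna_id[noncod]))
  cand <- intersect(cand, feature_ids(mirna_expr))
  cand <- setdiff(cand, pair$mirna_id)
  if (!length(cand)) return(NULL)
  if (!pair$mirna_id %in% feature_ids(mirna_expr)) {
    stop("miRNA ", pair$mirna_id, " absent from the expression matrix")
  }
  m1 <- mirna_expr$values[, pair$mirna_id]
  r <- vapply(cand, function(m2) {
    stats::cor(m1, mirna_expr$values[, m2])
  }, numeric(1))
  if (cfg$covariate_correlation == "absolute") r <- abs(r)
  # ties at the maximum go to the lexicographically smallest id
  cand[order(-r, cand)][1L]
}

#' Fit the nested models for one miRNA-gene pair
#'
#' Trains the full model (all transcripts of the pair universe, plus the
#' optional covariate miRNA) and the reduced model (escape transcripts
#' only, plus the same covariate) on the training samples, evaluates the
#' RMSE gate on the test samples (both models must score below the
#' threshold), and computes the likelihood-ratio test and Cohen's f2
#' from the training fits.
#'
#' @param pair A [pair_universe()].
#' @param transcript_expr,mirna_expr [expression_matrix()] objects
#'   sharing the split's sample ids.
#' @param split A [split_samples()] result.
#' @param cfg A [pipeline_config()].
#' @param covariate Optional covariate miRNA id (TNBN only).
#' @return List with `result` (named list of per-pair statistics),
#'   `cache` (training/test matrices and full-fit summaries reused by
#'   the label-permutation null) -- or, when the pair cannot be fitted,
#'   `skipped = TRUE` with a `reason`.
#' @export
fit_pair <- function(pair, transcript_expr, mirna_expr, split,
                     cfg = pipeline_config(), covariate = NULL) {
  all_ids <- c(split$train_ids, split$test_ids)
  missing_tx <- setdiff(pair$full, feature_ids(transcript_expr))
  if (length(missing_tx)) {
    return(list(skipped = TRUE,
                reason = paste0("transcript(s) absent from expression: ",
                                paste(missing_tx, collapse = ","))))
  }
  if (!pair$mirna_id %in% feature_ids(mirna_expr)) {
    return(list(skipped = TRUE, reason = "miRNA absent from expression"))
  }
  Xall <- transcript_expr$values[all_ids, pair$full, drop = FALSE]
  if (!is.null(covariate)) {
    if (!covariate %in% feature_ids(mirna_expr)) {
      return(list(skipped = TRUE, reason = "covariate miRNA absent from expression"))
    }
    Xall <- cbind(Xall, mirna_expr$values[all_ids, covariate, drop = FALSE])
  }
  y <- mirna_expr$values[all_ids, pair$mirna_id]
  tr <- seq_along(split$train_ids)
  te <- length(split$train_ids) + seq_along(split$test_ids)
  n_params_full <- ncol(Xall) + 1L
  if (length(tr) <= n_params_full) {
    return(list(skipped = TRUE,
                reason = sprintf("too few training samples (%d) for %d parameters",
                                 length(tr), n_params_full)))
  }
  red_cols <- c(pair$reduced, covariate)
  full_fit <- fit_ols(Xall[tr, , drop = FALSE], y[tr])
  red_fit <- fit_ols(Xall[tr, red_cols, drop = FALSE], y[tr])
  rmse_full <- rmse_on(full_fit, Xall[te, , drop = FALSE], y[te])
  rmse_red <- rmse_on(red_fit, Xall[te, , drop = FALSE], y[te])
  gate <- rmse_full < cfg$rmse_threshold && rmse_red < cfg$rmse_threshold
  if (full_fit$rss > 0) {
    lrt <- likelihood_ratio_test(full_fit, red_fit)
  } else {
    lrt <- list(lrt_stat = NA_real_, df = full_fit$n_params - red_fit$n_params,
                p = NA_real_)
  }
  f2 <- cohens_f2(full_fit$adj_r2, red_fit$adj_r2)
  k <- length(pair$reduced)
  l <- length(pair$full) - k
  result <- list(
    mirna = pair$mirna_id, gene = pair$gene_id, setting = pair$setting,
    k = k, l = l,
    covariate_mirna = if (is.null(covariate)) NA_character_ else covariate,
    rmse_full = rmse_full, rmse_reduced = rmse_red,
    passed_rmse_gate = gate,
    lrt_stat = lrt$lrt_stat, df = lrt$df, p = lrt$p,
    adj_r2_full = full_fit$adj_r2, adj_r2_reduced = red_fit$adj_r2,
    cohens_f2 = f2$f2, f2_bin = f2$bin,
    degenerate = full_fit$rank_deficient || red_fit$rank_deficient
  )
  cache <- list(
    X_train = Xall[tr, , drop = FALSE], X_test = Xall[te, , drop = FALSE],
    y_train = y[tr], y_test = y[te],
    full_ids = pair$full, reduced_ids = pair$reduced,
    covariate = covariate,
    rss_full = full_fit$rss, n_params_full = full_fit$n_params,
    rmse_full = rmse_full, n_train = length(tr)
  )
  list(result = result, cache = cache)
}

#' Fit the nested models for every pair universe
#'
#' Applies [fit_pair()] across a list of pair universes, assembling the
#' per-pair results table (with a global BH adjustment over the
#' gate-passing pairs in column `p_adj`), the skip log, and the fit
#' cache consumed by the randomization null.
#'
#' @inheritParams fit_pair
#' @param universes List of [pair_universe()] objects (one setting).
#' @param covariates Optional named-by-index list/vector of covariate
#'   miRNA ids aligned with `universes` (`NA`/`NULL` entries mean no
#'   covariate).
#' @return List of class `"pair_fits"`: `results` (data.frame),
#'   `skipped` (data.frame), `fits` (list of caches aligned with
#'   `results` rows), `universes` (the fitted universes).
#' @export
fit_all_pairs <- function(universes, transcript_expr, mirna_expr, split,
                          cfg = pipeline_config(), covariates = NULL) {
  n <- length(universes)
  rows <- vector("list", n)
  caches <- vector("list", n)
  kept_universes <- vector("list", n)
  skips <- vector("list", n)
  n_ok <- 0L; n_skip <- 0L
  for (i in seq_len(n)) {
    cov <- if (is.null(covariates)) NULL else covariates[[i]]
    if (!is.null(cov) && (length(cov) != 1L || is.na(cov))) cov <- NULL
    ft <- fit_pair(universes[[i]], transcript_expr, mirna_expr, split, cfg,
                   covariate = cov)
    if (isTRUE(ft$skipped)) {
      n_skip <- n_skip + 1L
      skips[[n_skip]] <- data.frame(
        mirna = universes[[i]]$mirna_id, gene = universes[[i]]$gene_id,
        setting = universes[[i]]$setting, reason = ft$reason,
        stringsAsFactors = FALSE)
    } else {
      n_ok <- n_ok + 1L
      rows[[n_ok]] <- as.data.frame(ft$result, stringsAsFactors = FALSE)
      caches[[n_ok]] <- ft$cache
      kept_universes[[n_ok]] <- universes[[i]]
    }
  }
  results <- if (n_ok) do.call(rbind, rows[seq_len(n_ok)]) else
    data.frame()
  if (n_ok) {
    results$p_adj <- NA_real_
    gated <- which(results$passed_rmse_gate & !is.na(results$p))
    if (length(gated)) {
      results$p_adj[gated] <- benjamini_hochberg(results$p[gated],
                                                 cfg$fdr_alpha)$p_adj
    }
  }
  skipped <- if (n_skip) do.call(rbind, skips[seq_len(n_skip)]) else
    data.frame(mirna = character(0), gene = character(0),
               setting = character(0), reason = character(0))
  sm_log("fitted %d pairs (%d skipped)", n_ok, n_skip)
  structure(list(results = results, skipped = skipped,
                 fits = caches[seq_len(n_ok)],
                 universes = kept_universes[seq_len(n_ok)]),
            class = "pair_fits")
}
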