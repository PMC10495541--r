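test_that("sample splits are sized, deterministic, and seed-sensitive", {
  ids <- sprintf("s%03d", 1:10)
  cfg <- pipeline_config(random_seed = 5)
  sp <- split_samples(ids, cfg)
  expect_length(sp$train_ids, 8L)
  expect_length(sp$test_ids, 2L)
  expect_setequal(c(sp$train_ids, sp$test_ids), ids)
  expect_identical(split_samples(ids, cfg), sp)

  ids100 <- sprintf("s%03d", 1:100)
  differs <- vapply(1:50, function(s) {
    a <- split_samples(ids100, pipeline_config(random_seed = s))
    b <- split_samples(ids100, pipeline_config(random_seed = s + 1))
    !identical(a$train_ids, b$train_ids)
  }, logical(1))
  expect_true(all(differs))
  expect_error(split_samples(ids[1:5], cfg), "at least 10")
})

test_that("OLS reproduces exact and normal-equation solutions", {
  # noiseless line: y = 2 t + 1
  t <- c(0, 1, 2, 3, 4)
  f <- fit_ols(cbind(t = t), 2 * t + 1)
  expect_equal(unname(f$coefficients), c(1, 2), tolerance = 1e-12)
  expect_equal(f$rss, 0, tolerance = 1e-20)
  expect_equal(f$adj_r2, 1, tolerance = 1e-12)

  set.seed(1)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(20)
  f2 <- fit_ols(X, y)
  expect_equal(unname(f2$coefficients), unname(ols_oracle(X, y)),
               tolerance = 1e-8)
  expect_false(f2$rank_deficient)
  expect_equal(f2$n_params, 4L)
})

test_that("rank-deficient designs flag degeneracy with unchanged projection", {
  set.seed(2)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(20)
  Xdup <- cbind(X, b2 = X[, "b"])
  fd <- fit_ols(Xdup, y)
  fc <- fit_ols(X, y)
  expect_true(fd$rank_deficient)
  expect_false(fc$rank_deficient)
  expect_equal(fd$rss, fc$rss, tolerance = 1e-9)  # same projection
})

test_that("RMSE evaluates held-out predictions", {
  t <- c(0, 1, 2, 3, 4)
  f <- fit_ols(cbind(t = t), 2 * t + 1)
  expect_equal(rmse_on(f, cbind(t = c(5, 6)), c(11, 13)), 0, tolerance = 1e-10)
  # residuals (1, -1) -> RMSE 1
  expect_equal(rmse_on(f, cbind(t = c(5, 6)), c(12, 12)), 1, tolerance = 1e-10)
  expect_error(rmse_on(f, cbind(t = numeric(0)), numeric(0)), "empty")
  expect_error(rmse_on(f, cbind(z = c(1, 2)), c(1, 2)), "lack column")
})

test_that("likelihood-ratio test follows the Gaussian-MLE closed form", {
  set.seed(3)
  X <- matrix(rnorm(150), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(50)
  full <- fit_ols(X, y)
  red <- fit_ols(X[, "a", drop = FALSE], y)
  lrt <- likelihood_ratio_test(full, red)
  expect_equal(lrt$lrt_stat, 50 * log(red$rss / full$rss), tolerance = 1e-12)
  expect_equal(lrt$df, 2L)
  expect_equal(lrt$p, pchisq(lrt$lrt_stat, 2, lower.tail = FALSE),
               tolerance = 1e-12)

  # identical RSS -> statistic 0, p = 1
  same <- likelihood_ratio_test(full, full0 <- fit_ols(X[, c("a", "b")], y))
  expect_gte(same$lrt_stat, 0)
  fr <- fit_ols(X[, c("a", "b")], y)
  fake_red <- fr; fake_red$rss <- full$rss
  expect_equal(likelihood_ratio_test(full, fake_red)$p, 1)

  # the worked example: n = 50, RSS ratio 2, df = 2
  fake_full <- full; fake_full$rss <- 5
  fake_red2 <- red; fake_red2$rss <- 10
  lrt2 <- likelihood_ratio_test(fake_full, fake_red2)
  expect_equal(lrt2$lrt_stat, 50 * log(2), tolerance = 1e-12)
  expect_equal(lrt2$p, pchisq(50 * log(2), 2, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_error(likelihood_ratio_test(red, full), "not nested")
  # p is monotone decreasing in the statistic at fixed df
  lam <- seq(0.1, 20, length.out = 30)
  expect_true(all(diff(pchisq(lam, 2, lower.tail = FALSE)) < 0))
})

test_that("nesting keeps RSS_full <= RSS_reduced", {
  set.seed(4)
  for (i in 1:50) {
    n <- sample(20:60, 1)
    X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("t", 1:4)))
    y <- rnorm(n)
    keep <- sample(1:4, sample(1:3, 1))
    full <- fit_ols(X, y)
    red <- fit_ols(X[, keep, drop = FALSE], y)
    expect_lte(full$rss, red$rss + 1e-9)
  }
})

test_that("BH adjustment matches the step-up rule and flags at alpha", {
  bh <- benjamini_hochberg(c(0.01, 0.02, 0.03), alpha = 0.05)
  expect_equal(bh$p_adj, c(0.03, 0.03, 0.03))
  expect_equal(bh$significant, c(TRUE, TRUE, TRUE))
  expect_equal(benjamini_hochberg(rep(1, 5))$p_adj, rep(1, 5))
  expect_false(any(benjamini_hochberg(rep(1, 5))$significant))
  expect_equal(benjamini_hochberg(0.2)$p_adj, 0.2)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Cohen's f2 follows the adjusted-R2 formula with standard bins", {
  expect_equal(cohens_f2(0.3, 0.3)$f2, 0)
  expect_equal(cohens_f2(0.3, 0.3)$bin, "none")
  f <- cohens_f2(0.5, 0.2)
  expect_equal(f$f2, 0.6, tolerance = 1e-12)
  expect_equal(f$bin, "large")
  f2 <- cohens_f2(0.1, 0.08)
  expect_equal(f2$f2, 0.02 / 0.9, tolerance = 1e-12)
  expect_equal(f2$bin, "small")
  expect_warning(out <- cohens_f2(1, 0.5), "undefined")
  expect_true(is.na(out$f2))
})

test_that("covariate miRNA selection maximizes correlation deterministically", {
  ann <- rbind(tm1("a", "g1"), tm1("b", "g1"))
  pair <- pair_universe("m1", "g1", "TNBN", full = c("a", "b"), reduced = "a")
  set.seed(5)
  n <- 50
  m1 <- rnorm(n)
  strong <- m1 * 0.9 + rnorm(n, 0, 0.2)
  weak <- m1 * 0.2 + rnorm(n)
  mi <- make_em(cbind(m1, strong, weak, strong), "mirna",
                features = c("m1", "m2", "m3", "m4"))
  # m2 and m3 have non-coding sites (> 0.5); m4 only a coding site
  sites <- rbind(site_row("m2", "b", 800, 807, 0.6),
                 site_row("m3", "a", 10, 17, 0.7),
                 site_row("m4", "b", 200, 207, 0.9))
  expect_equal(select_covariate_mirna(pair, sites, ann, mi), "m2")
  # tie between m2 and m4 (identical expression): if m4 also had a
  # non-coding site the lexicographically smaller id wins
  sites2 <- rbind(sites, site_row("m4", "b", 810, 817, 0.9))
  expect_equal(select_covariate_mirna(pair, sites2, ann, mi), "m2")
  # no candidate at all -> NULL
  expect_null(select_covariate_mirna(
    pair, site_row("m2", "b", 200, 207, 0.9), ann, mi))
  expect_error(select_covariate_mirna(
    pair_universe("m1", "g1", "ALLT", c("a", "b"), "a"), sites, ann, mi),
    "TNBN")
})

test_that("fit_pair detects a planted escape effect and stays null without", {
  d <- planted_pair_data(n = 200, effect = 0.8, noise = 0.05, seed = 10)
  cfg <- pipeline_config(random_seed = 2)
  sp <- split_samples(sample_ids(d$tx), cfg)
  ft <- fit_pair(d$pair, d$tx, d$mi, sp, cfg)
  expect_false(isTRUE(ft$skipped))
  expect_lt(ft$result$p, 0.01)
  expect_equal(ft$result$f2_bin, "large")
  expect_true(ft$result$passed_rmse_gate)
  expect_equal(ft$result$k, 1L)
  expect_equal(ft$result$l, 1L)
  expect_equal(ft$result$df, 1L)

  # binding transcript pure noise -> approximately uniform p-values
  pv <- vapply(1:200, function(s) {
    d0 <- planted_pair_data(n = 60, effect = 0, noise = 0.3, seed = 1000 + s)
    sp0 <- split_samples(sample_ids(d0$tx), cfg)
    fit_pair(d0$pair, d0$tx, d0$mi, sp0, cfg)$result$p
  }, numeric(1))
  expect_lt(suppressWarnings(ks.test(pv, "punif")$statistic), 0.1)

  # a covariate that is (nearly) the response miRNA saturates the reduced
  # model: the binding transcript adds nothing and significance vanishes
  pv_sat <- vapply(1:40, function(s) {
    d2 <- planted_pair_data(n = 200, effect = 0.8, noise = 0.3,
                            seed = 4000 + s)
    set.seed(s)
    mi2 <- make_em(cbind(d2$mi$values[, 1],
                         d2$mi$values[, 1] + rnorm(200, 0, 0.01)), "mirna",
                   samples = sample_ids(d2$mi), features = c("miR-1", "miR-2"))
    fit_pair(d2$pair, d2$tx, mi2, sp, cfg, covariate = "miR-2")$result$p
  }, numeric(1))
  expect_lte(mean(pv_sat < 0.05), 0.1)
  # whereas without the covariate the same pairs are all significant
  p_free <- vapply(1:10, function(s) {
    d2 <- planted_pair_data(n = 200, effect = 0.8, noise = 0.3,
                            seed = 4000 + s)
    fit_pair(d2$pair, d2$tx, d2$mi, sp, cfg)$result$p
  }, numeric(1))
  expect_true(all(p_free < 1e-6))

  # too few samples for the parameter count -> skipped with a reason
  tiny_ids <- sample_ids(d$tx)[1:12]
  tx_t <- splicemir:::em_subset(d$tx, samples = tiny_ids)
  mi_t <- splicemir:::em_subset(d$mi, samples = tiny_ids)
  sp_t <- split_samples(tiny_ids, pipeline_config(train_fraction = 0.2,
                                                  random_seed = 1))
  ft3 <- fit_pair(d$pair, tx_t, mi_t, sp_t,
                  pipeline_config(train_fraction = 0.2, random_seed = 1))
  expect_true(isTRUE(ft3$skipped))
  expect_match(ft3$reason, "too few")
})

test_that("planted regression slope is recovered within 3 standard errors", {
  # with effect 0.8, miRNA sd 0.5, noise sd 0.3 the population slope of
  # the binding transcript in the m ~ t regression is
  # -e*sd_m^2/(e^2*sd_m^2 + sd_n^2) = -0.8
  hits <- vapply(1:200, function(s) {
    d <- planted_pair_data(n = 500, effect = 0.8, noise = 0.3,
                           mirna_sd = 0.5, seed = 3000 + s)
    df <- data.frame(m = d$mi$values[, 1], tA = d$tx$values[, "tA"],
                     tB = d$tx$values[, "tB"])
    sm <- summary(lm(m ~ tA + tB, data = df))$coefficients
    abs(sm["tB", "Estimate"] - (-0.8)) <= 3 * sm["tB", "Std. Error"]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("fit_all_pairs assembles results, skips, and global BH", {
  d <- planted_pair_data(n = 100, effect = 0.8, noise = 0.1, seed = 12)
  cfg <- pipeline_config(random_seed = 4)
  sp <- split_samples(sample_ids(d$tx), cfg)
  bundle <- quiet(fit_all_pairs(list(d$pair), d$tx, d$mi, sp, cfg))
  expect_s3_class(bundle, "pair_fits")
  expect_equal(nrow(bundle$results), 1L)
  expect_equal(nrow(bundle$skipped), 0L)
  expect_equal(bundle$results$p_adj, bundle$results$p)  # single test
  expect_length(bundle$fits, 1L)
})
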