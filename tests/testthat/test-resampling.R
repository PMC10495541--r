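make_results <- function(p, gate = TRUE) {
  n <- length(p)
  data.frame(mirna = sprintf("m%04d", seq_len(n)),
             gene = sprintf("g%04d", seq_len(n)), setting = "TNBN",
             p = p, passed_rmse_gate = rep_len(gate, n),
             p_adj = p.adjust(p, "BH"), stringsAsFactors = FALSE)
}

test_that("subsampled ratios behave on degenerate and planted inputs", {
  cfg <- pipeline_config(subsample_size = 50, subsample_iterations = 20,
                         random_seed = 1)
  # all p = 1 -> every ratio 0
  rs <- subsample_significance_ratio(make_results(rep(1, 200)), cfg)
  expect_equal(rs$ratio, rep(0, 20))
  expect_false(any(rs$randomized))
  expect_equal(rs$n_pairs_tested, rep(50L, 20))

  # subsample covering the whole set -> identical ratios in all iterations
  cfg_all <- pipeline_config(subsample_size = 200, subsample_iterations = 10,
                             random_seed = 1)
  set.seed(42)
  p <- c(runif(140), rexp(60, 2000))  # 30% strong effects
  rs2 <- quiet(subsample_significance_ratio(make_results(p), cfg_all))
  expect_length(unique(rs2$ratio), 1L)

  # subsampled mean tracks the full-set ratio
  cfg_sub <- pipeline_config(subsample_size = 60, subsample_iterations = 100,
                             random_seed = 2)
  full_ratio <- mean(p.adjust(p, "BH") < 0.05)
  rs3 <- subsample_significance_ratio(make_results(p), cfg_sub)
  expect_lt(abs(mean(rs3$ratio) - full_ratio), 0.05)

  # gate-failing pairs never enter numerator or denominator
  half_gate <- make_results(rep(1e-8, 100), gate = c(TRUE, FALSE))
  rs4 <- subsample_significance_ratio(
    half_gate, pipeline_config(subsample_size = 100,
                               subsample_iterations = 5, random_seed = 3))
  expect_equal(rs4$n_pairs_tested, rep(50L, 5))
  expect_equal(rs4$ratio, rep(1, 5))

  expect_error(subsample_significance_ratio(data.frame(), cfg), "empty")
})

test_that("label shuffling is uniform over configurations and count-preserving", {
  pair <- pair_universe("m", "g", "ALLT", full = c("a", "b"), reduced = "a")
  set.seed(7)
  draws <- replicate(10000, randomize_binding_labels(pair)$reduced)
  freq <- table(draws) / 10000
  expect_equal(unname(freq[["a"]]), 0.5, tolerance = 0.04)  # 50% +/- 2pp
  expect_equal(unname(freq[["b"]]), 0.5, tolerance = 0.04)

  # counts preserved on every draw
  pair4 <- pair_universe("m", "g", "ALLT", full = letters[1:4],
                         reduced = c("a", "b"))
  for (i in 1:200) {
    sh <- randomize_binding_labels(pair4)
    expect_length(sh$reduced, 2L)
    expect_setequal(sh$full, pair4$full)
  }

  # seeded shuffles reproduce
  expect_identical(randomize_binding_labels(pair4, seed = 9)$reduced,
                   randomize_binding_labels(pair4, seed = 9)$reduced)
})

test_that("identity shuffles reproduce the original reduced fit exactly", {
  d <- planted_pair_data(n = 100, effect = 0.8, noise = 0.2, seed = 21)
  cfg <- pipeline_config(random_seed = 6)
  sp <- split_samples(sample_ids(d$tx), cfg)
  ft <- fit_pair(d$pair, d$tx, d$mi, sp, cfg)
  cc <- ft$cache
  # find an identity shuffle and refit the reduced model the same way the
  # randomized pipeline does
  sh <- NULL
  for (s in 1:50) {
    cand <- randomize_binding_labels(d$pair, seed = s)
    if (identical(sort(cand$reduced), sort(d$pair$reduced))) { sh <- cand; break }
  }
  expect_false(is.null(sh))
  refit <- fit_ols(cc$X_train[, sh$reduced, drop = FALSE], cc$y_train)
  orig <- fit_ols(cc$X_train[, d$pair$reduced, drop = FALSE], cc$y_train)
  expect_identical(refit$rss, orig$rss)
  # the full model is untouched by any shuffle: same full set, same fit
  full_a <- fit_ols(cc$X_train[, d$pair$full, drop = FALSE], cc$y_train)
  full_b <- fit_ols(cc$X_train[, randomize_binding_labels(d$pair, 3)$full,
                               drop = FALSE], cc$y_train)
  expect_identical(full_a$coefficients[sort(names(full_a$coefficients))],
                   full_b$coefficients[sort(names(full_b$coefficients))])
})

test_that("randomized ratios fall below real ratios under planted coupling", {
  sim <- simulation_config(n_genes = 60, n_mirnas = 8, n_samples = 150,
                           frac_regulated_pairs = 0.4, effect_size = 0.8,
                           noise_sd = 0.3, seed = 31)
  ds <- make_dataset(sim)
  cfg <- pipeline_config(subsample_size = 80, subsample_iterations = 40,
                         random_seed = 13)
  run <- quiet(run_pipeline(cfg, ds$mirna, ds$transcript, ds$gene, ds$sites,
                            ds$annotation, setting = "TNBN"))
  real <- run$ratios[!run$ratios$randomized, ]
  rand <- run$ratios[run$ratios$randomized, ]
  expect_gt(mean(real$ratio), mean(rand$ratio))
  expect_lt(run$comparison$p_value, 0.05)
  expect_equal(run$comparison$dist,
               mean(real$ratio) - mean(rand$ratio), tolerance = 1e-12)
})

test_that("distribution comparison: exact, approximate and degenerate paths", {
  mk <- function(r, randomized) data.frame(iteration = seq_along(r), ratio = r,
                                           randomized = randomized,
                                           n_pairs_tested = 10L)
  # identical non-constant samples -> maximal p, zero dist
  x <- c(0.1, 0.2, 0.3, 0.4)
  cmp <- compare_ratio_distributions(mk(x, FALSE), mk(x, TRUE))
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$dist, 0)

  # complete separation at n = m = 4: exact two-sided p = 2/70
  cmp2 <- compare_ratio_distributions(mk(rep(0.9, 4), FALSE),
                                      mk(rep(0.1, 4), TRUE))
  expect_equal(cmp2$p_value, 2 / 70, tolerance = 1e-12)
  expect_equal(cmp2$u_statistic, 16)
  expect_equal(cmp2$dist, 0.8, tolerance = 1e-12)

  # all pooled values tied -> degenerate comparison
  cmp3 <- compare_ratio_distributions(mk(rep(0, 30), FALSE), mk(rep(0, 30), TRUE))
  expect_equal(cmp3$p_value, 1)
  expect_equal(cmp3$u_statistic, 450)

  # flags must be homogeneous and correctly oriented
  expect_error(compare_ratio_distributions(mk(x, TRUE), mk(x, TRUE)),
               "randomized")
  expect_error(compare_ratio_distributions(mk(x, FALSE), mk(x, FALSE)),
               "non-randomized")

  # exact branch agrees with wilcox.test's exact p on untied data
  set.seed(8)
  a <- rnorm(8); b <- rnorm(8) + 0.5
  cmp4 <- compare_ratio_distributions(mk(a, FALSE), mk(b, TRUE))
  ref <- wilcox.test(a, b, exact = TRUE)
  expect_equal(cmp4$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(cmp4$u_statistic, unname(ref$statistic))
})

test_that("the comparison has power against a 2-sigma shift", {
  mk <- function(r, randomized) data.frame(iteration = seq_along(r), ratio = r,
                                           randomized = randomized,
                                           n_pairs_tested = 10L)
  set.seed(15)
  sig <- vapply(1:30, function(i) {
    x <- rnorm(100, 0.5, 0.05)
    y <- rnorm(100, 0.4, 0.05)  # shift = 2 sigma
    compare_ratio_distributions(mk(x, FALSE), mk(y, TRUE))$p_value < 0.05
  }, logical(1))
  expect_true(all(sig))
})
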