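# Shared builders and independent oracles for the test suite.

quiet <- function(expr) withr::with_options(list(splicemir.verbose = FALSE), expr)

# one annotation row as used throughout: 5'UTR [0,100), CDS [100,700),
# 3'UTR [700,1000)
tm1 <- function(id = "t1", gene = "g1", length = 1000L,
                cds_start = 100L, cds_end = 700L) {
  data.frame(transcript_id = id, gene_id = gene, length = length,
             cds_start = cds_start, cds_end = cds_end,
             stringsAsFactors = FALSE)
}

site_row <- function(mirna, tx, start, end, p) {
  data.frame(mirna_id = mirna, transcript_id = tx, start = as.integer(start),
             end = as.integer(end), probability = p, stringsAsFactors = FALSE)
}

make_em <- function(values, kind, samples = NULL, features = NULL,
                    floor = log2(0.001)) {
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(nrow(values)))
  if (is.null(features)) features <- sprintf("f%02d", seq_len(ncol(values)))
  dimnames(values) <- list(samples, features)
  expression_matrix(values, kind, floor)
}

# independent per-nucleotide membership oracle for site-region assignment
region_oracle <- function(start, end, cds_start, cds_end, length) {
  nts <- seq(start, end - 1L)
  coding_nt <- nts >= cds_start & nts < cds_end
  out <- character(0)
  if (any(coding_nt)) out <- c(out, "coding")
  if (any(!coding_nt)) out <- c(out, "noncoding")
  out
}

# independent restatement of the four-way binding classification rules
category_oracle <- function(probs, regions, low = 0.5, high = 0.8) {
  if (length(probs) == 0L || !any(probs > low)) return("NON_BINDING")
  hi <- probs > high
  if (!any(hi)) return("DISCARD")
  r <- unique(unlist(regions[hi]))
  if (all(c("coding", "noncoding") %in% r)) "BOTH"
  else if ("coding" %in% r) "CODING_ONLY"
  else "NONCODING_ONLY"
}

# hand-rolled BH step-up: p_(i) * m / i with cumulative minimum from the top
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  adj_sorted <- pmin(adj_sorted, 1)
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# normal-equation OLS oracle
ols_oracle <- function(X, y) {
  D <- cbind(1, X)
  drop(solve(t(D) %*% D, t(D) %*% y))
}

# small planted miRNA-gene pair: one escape transcript (noise), one
# binding transcript negatively coupled to the miRNA
planted_pair_data <- function(n = 200, effect = 0.8, noise = 0.3,
                              mirna_sd = 0.5, seed = 1) {
  set.seed(seed)
  m <- 6 + mirna_sd * rnorm(n)
  t_nb <- 5 + rnorm(n, 0, noise)
  t_b <- 5 - effect * (m - 6) + rnorm(n, 0, noise)
  samples <- sprintf("s%03d", seq_len(n))
  tx <- make_em(cbind(t_nb, t_b), "transcript", samples, c("tA", "tB"))
  mi <- make_em(cbind(m), "mirna", samples, "miR-1")
  list(tx = tx, mi = mi,
       pair = pair_universe("miR-1", "g1", "TNBN",
                            full = c("tA", "tB"), reduced = "tA"))
}
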