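#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. The generator emulates
#' the statistical structure the analysis assumes: multi-transcript
#' genes with coding/non-coding regions, high- and intermediate-
#' confidence target sites around the 0.5/0.8 probability cutoffs, and
#' log2-scale expression in which binding transcripts are negatively
#' coupled to the driving miRNA while escape transcripts are not.
#'
#' @param n_genes Number of genes.
#' @param transcripts_per_gene Integer range `c(min, max)` of isoforms
#'   per gene (default 2..4; min >= 2 whenever regulated pairs exist, so
#'   every regulated gene has an escape isoform).
#' @param n_mirnas Number of miRNAs.
#' @param n_samples Number of samples.
#' @param frac_regulated_pairs Fraction of all (miRNA, gene) pairs that
#'   are truly regulated (default 0.3).
#' @param effect_size Coupling coefficient, log2 units: a binding
#'   transcript loses `effect_size` log2 units per log2 unit of miRNA
#'   above its mean (default 0.8).
#' @param noise_sd Gaussian noise on transcript expression (default 0.3).
#' @param baseline_mean,baseline_sd Per-transcript baseline log2
#'   expression (defaults 5 and 1).
#' @param mirna_mean,mirna_sd miRNA log2 expression distribution
#'   (defaults 6 and 0.5; the sd is the scale against which the
#'   test-RMSE gate of 0.7 log2 units is meaningful -- an uninformative
#'   reduced model has test RMSE near `mirna_sd`).
#' @param frac_coding_sites,frac_noncoding_sites,frac_both Mixture over
#'   the region in which a regulated pair's sites are placed (normalized
#'   internally; defaults 1/0/0).
#' @param prob_high_range Probability range for planted high-confidence
#'   sites, inside (0.8, 1].
#' @param prob_mid_range Range for decoy intermediate sites, inside
#'   (0.5, 0.8].
#' @param decoy_rate Fraction of unregulated (miRNA, gene) pairs that
#'   receive one intermediate-confidence decoy site (default 0.05),
#'   exercising the discard rule downstream.
#' @param confound_fraction Fraction of regulated pairs whose binding
#'   transcript responds to a correlated partner miRNA (which binds the
#'   gene's non-coding region) instead of the labelled miRNA
#'   (default 0).
#' @param confound_loading Shared-factor loading lambda inducing
#'   correlation lambda^2 between partner miRNAs (default 0.8).
#' @param seed Integer seed; topology and expression are fully
#'   deterministic given the config.
#' @return List of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 50L,
                              transcripts_per_gene = c(2L, 4L),
                              n_mirnas = 10L,
                              n_samples = 200L,
                              frac_regulated_pairs = 0.3,
                              effect_size = 0.8,
                              noise_sd = 0.3,
                              baseline_mean = 5, baseline_sd = 1,
                              mirna_mean = 6, mirna_sd = 0.5,
                              frac_coding_sites = 1,
                              frac_noncoding_sites = 0,
                              frac_both = 0,
                              prob_high_range = c(0.85, 0.99),
                              prob_mid_range = c(0.55, 0.79),
                              decoy_rate = 0.05,
                              confound_fraction = 0,
                              confound_loading = 0.8,
                              seed = 1L) {
  stopifnot(
    n_genes >= 1, n_mirnas >= 1, n_samples >= 2,
    length(transcripts_per_gene) == 2L,
    transcripts_per_gene[1L] >= 1, diff(transcripts_per_gene) >= 0,
    frac_regulated_pairs >= 0, frac_regulated_pairs <= 1,
    noise_sd > 0, mirna_sd > 0, baseline_sd >= 0,
    frac_coding_sites >= 0, frac_noncoding_sites >= 0, frac_both >= 0,
    frac_coding_sites + frac_noncoding_sites + frac_both > 0,
    prob_high_range[1L] > 0.8, prob_high_range[2L] <= 1,
    prob_high_range[1L] <= prob_high_range[2L],
    prob_mid_range[1L] > 0.5, prob_mid_range[2L] <= 0.8,
    prob_mid_range[1L] <= prob_mid_range[2L],
    decoy_rate >= 0, decoy_rate <= 1,
    confound_fraction >= 0, confound_fraction <= 1,
    confound_loading >= 0, confound_loading <= 1
  )
  if (frac_regulated_pairs > 0 && transcripts_per_gene[1L] < 2L) {
    stop("regulated pairs need transcripts_per_gene >= 2 (an escape isoform)")
  }
  structure(as.list(environment()), class = "simulation_config")
}

# partner miRNA index for the shared-factor couples (1,2), (3,4), ...
partner_index <- function(i, n_mirnas) {
  p <- if (i %% 2L == 1L) i + 1L else i - 1L
  if (p >= 1L && p <= n_mirnas) p else NA_integer_
}

#' Generate gene/transcript topology, target sites, and ground truth
#'
#' Draws gene models (transcript lengths and CDS intervals), selects
#' regulated (miRNA, gene) pairs, plants high-confidence sites on a
#' proper subset of each regulated gene's transcripts (so every
#' regulated pair survives the alternative-splicing filter by
#' construction), and sprinkles intermediate-confidence decoy sites on
#' unregulated pairs to exercise the discard rule. With
#' `confound_fraction > 0`, eligible regulated pairs are driven by a
#' correlated partner miRNA that also receives a non-coding site on the
#' gene (making it a covariate candidate).
#'
#' @param sim A [simulation_config()].
#' @return List with `annotation` (data.frame), `sites` (data.frame as
#'   from [read_site_predictions()]), and `truth` (list: `pairs`
#'   data.frame with `mirna_id`, `gene_id`, `region`, `driver_mirna`,
#'   `confounded`, `effect`; `binding` data.frame mapping pairs to
#'   binding transcript ids).
#' @export
generate_topology <- function(sim) {
  stopifnot(inherits(sim, "simulation_config"))
  set.seed(sim$seed)
  gene_ids <- sprintf("g%04d", seq_len(sim$n_genes))
  mirna_ids <- sprintf("miR-%03d", seq_len(sim$n_mirnas))
  nt_range <- seq(sim$transcripts_per_gene[1L], sim$transcripts_per_gene[2L])
  nt <- if (length(nt_range) == 1L) rep(nt_range, sim$n_genes) else
    sample(nt_range, sim$n_genes, replace = TRUE)
  ann <- do.call(rbind, lapply(seq_len(sim$n_genes), function(g) {
    len <- sample(900:3000, nt[g], replace = TRUE)
    utr5 <- sample(100:300, nt[g], replace = TRUE)
    utr3 <- sample(100:300, nt[g], replace = TRUE)
    data.frame(
      transcript_id = sprintf("%s.t%d", gene_ids[g], seq_len(nt[g])),
      gene_id = gene_ids[g], length = len,
      cds_start = utr5, cds_end = len - utr3,
      stringsAsFactors = FALSE)
  }))
  combos <- expand.grid(mirna_id = mirna_ids, gene_id = gene_ids,
                        stringsAsFactors = FALSE)
  n_reg <- round(sim$frac_regulated_pairs * nrow(combos))
  reg_idx <- if (n_reg > 0) sample.int(nrow(combos), n_reg) else integer(0)

  region_probs <- c(sim$frac_coding_sites, sim$frac_noncoding_sites,
                    sim$frac_both)
  region_probs <- region_probs / sum(region_probs)

  site_rows <- list()
  pair_rows <- list()
  bind_rows <- list()
  place_site <- function(mirna, tx_row, region, prob) {
    w <- 7L
    start <- switch(region,
      coding = sample(tx_row$cds_start:(tx_row$cds_end - w), 1L),
      noncoding = sample(tx_row$cds_end:(tx_row$length - w), 1L),
      both = tx_row$cds_end - 3L)
    data.frame(mirna_id = mirna, transcript_id = tx_row$transcript_id,
               start = start, end = start + w, probability = prob,
               stringsAsFactors = FALSE)
  }
  for (r in seq_along(reg_idx)) {
    m <- combos$mirna_id[reg_idx[r]]
    g <- combos$gene_id[reg_idx[r]]
    txs <- ann[ann$gene_id == g, , drop = FALSE]
    n_bind <- sample.int(nrow(txs) - 1L, 1L)
    bind_tx <- sample(txs$transcript_id, n_bind)
    region <- c("coding", "noncoding", "both")[
      sample.int(3L, 1L, prob = region_probs)]
    m_idx <- match(m, mirna_ids)
    p_idx <- partner_index(m_idx, sim$n_mirnas)
    confounded <- !is.na(p_idx) && stats::runif(1) < sim$confound_fraction
    driver <- if (confounded) mirna_ids[p_idx] else m
    for (tx in bind_tx) {
      tx_row <- txs[txs$transcript_id == tx, ]
      prob <- stats::runif(1, sim$prob_high_range[1L], sim$prob_high_range[2L])
      site_rows[[length(site_rows) + 1L]] <- place_site(m, tx_row, region, prob)
    }
    if (confounded) {
      # the partner binds the non-coding region of some transcript of g,
      # qualifying it as a covariate candidate (> 0.5 suffices)
      tx_row <- txs[sample.int(nrow(txs), 1L), ]
      prob <- stats::runif(1, sim$prob_mid_range[1L], sim$prob_mid_range[2L])
      site_rows[[length(site_rows) + 1L]] <-
        place_site(mirna_ids[p_idx], tx_row, "noncoding", prob)
    }
    pair_rows[[r]] <- data.frame(
      mirna_id = m, gene_id = g, region = region, driver_mirna = driver,
      confounded = confounded, effect = sim$effect_size,
      stringsAsFactors = FALSE)
    bind_rows[[r]] <- data.frame(mirna_id = m, gene_id = g,
                                 transcript_id = bind_tx,
                                 stringsAsFactors = FALSE)
  }
  unreg <- setdiff(seq_len(nrow(combos)), reg_idx)
  n_decoy <- round(sim$decoy_rate * length(unreg))
  if (n_decoy > 0) {
    for (d in sample(unreg, n_decoy)) {
      g <- combos$gene_id[d]
      txs <- ann[ann$gene_id == g, , drop = FALSE]
      tx_row <- txs[sample.int(nrow(txs), 1L), ]
      prob <- stats::runif(1, sim$prob_mid_range[1L], sim$prob_mid_range[2L])
      region <- c("coding", "noncoding")[sample.int(2L, 1L)]
      site_rows[[length(site_rows) + 1L]] <-
        place_site(combos$mirna_id[d], tx_row, region, prob)
    }
  }
  sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(mirna_id = character(0), transcript_id = character(0),
               start = integer(0), end = integer(0),
               probability = numeric(0), stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(mirna_id = character(0), gene_id = character(0),
               region = character(0), driver_mirna = character(0),
               confounded = logical(0), effect = numeric(0),
               stringsAsFactors = FALSE)
  binding <- if (length(bind_rows)) do.call(rbind, bind_rows) else
    data.frame(mirna_id = character(0), gene_id = character(0),
               transcript_id = character(0), stringsAsFactors = FALSE)
  rownames(pairs) <- rownames(binding) <- NULL
  list(annotation = ann, sites = sites,
       truth = list(pairs = pairs, binding = binding))
}

#' Generate coupled miRNA / transcript / gene expression
#'
#' miRNA expression is Gaussian on the log2 scale (partner miRNAs share
#' a latent factor when confounding is configured). Each binding
#' transcript of a regulated pair loses `effect * (m_driver - mirna_mean)`
#' log2 units; escape transcripts are baseline plus noise. Gene
#' expression is the log2 of the summed linear-scale transcript
#' abundances, so the correlation filter sees realistic gene-level
#' coupling. A transcript binding several regulated miRNAs accumulates
#' their effects.
#'
#' @param topology Output of [generate_topology()].
#' @param sim The same [simulation_config()].
#' @return List of three [expression_matrix()] objects: `mirna`,
#'   `transcript`, `gene`, sharing sample ids `s0001...`.
#' @export
generate_expression <- function(topology, sim) {
  stopifnot(inherits(sim, "simulation_config"))
  set.seed(sim$seed + 104729L)
  ns <- sim$n_samples
  samples <- sprintf("s%04d", seq_len(ns))
  mirna_ids <- sprintf("miR-%03d", seq_len(sim$n_mirnas))

  lam <- sim$confound_loading
  use_factor <- sim$confound_fraction > 0 && lam > 0
  M <- matrix(NA_real_, ns, sim$n_mirnas,
              dimnames = list(samples, mirna_ids))
  if (use_factor) {
    n_couples <- ceiling(sim$n_mirnas / 2)
    Z <- matrix(stats::rnorm(ns * n_couples), ns, n_couples)
    for (i in seq_len(sim$n_mirnas)) {
      z <- Z[, ceiling(i / 2)]
      e <- stats::rnorm(ns)
      M[, i] <- sim$mirna_mean + sim$mirna_sd * (lam * z + sqrt(1 - lam^2) * e)
    }
  } else {
    M[] <- sim$mirna_mean + sim$mirna_sd * stats::rnorm(ns * sim$n_mirnas)
  }

  ann <- topology$annotation
  ntx <- nrow(ann)
  base <- stats::rnorm(ntx, sim$baseline_mean, sim$baseline_sd)
  TX <- matrix(stats::rnorm(ns * ntx, 0, sim$noise_sd), ns, ntx,
               dimnames = list(samples, ann$transcript_id))
  TX <- sweep(TX, 2L, -base)   # add per-transcript baseline
  pairs <- topology$truth$pairs
  binding <- topology$truth$binding
  if (nrow(binding)) {
    key <- paste(pairs$mirna_id, pairs$gene_id, sep = "\r")
    drv <- stats::setNames(pairs$driver_mirna, key)
    eff <- stats::setNames(pairs$effect, key)
    for (i in seq_len(nrow(binding))) {
      k <- paste(binding$mirna_id[i], binding$gene_id[i], sep = "\r")
      e <- eff[[k]]
      if (e != 0) {
        m <- M[, drv[[k]]]
        TX[, binding$transcript_id[i]] <-
          TX[, binding$transcript_id[i]] - e * (m - sim$mirna_mean)
      }
    }
  }
  gene_ids <- unique(ann$gene_id)
  G <- matrix(NA_real_, ns, length(gene_ids),
              dimnames = list(samples, gene_ids))
  lin <- 2^TX
  for (g in gene_ids) {
    txs <- ann$transcript_id[ann$gene_id == g]
    G[, g] <- log2(rowSums(lin[, txs, drop = FALSE]))
  }
  list(mirna = expression_matrix(M, "mirna"),
       transcript = expression_matrix(TX, "transcript"),
       gene = expression_matrix(G, "gene"))
}

#' Generate a complete synthetic dataset bundle
#'
#' Convenience wrappers around [generate_topology()] and
#' [generate_expression()]. `make_null_dataset()` forces the coupling
#' to zero while leaving the topology (and hence the site table and the
#' pairs admitted by the alternative-splicing filter) unchanged, which
#' makes it the type-I-error control: pairs are analyzable but carry no
#' signal.
#'
#' @param sim A [simulation_config()].
#' @return List with `annotation`, `sites`, `truth`, `mirna`,
#'   `transcript`, `gene`, `sim`.
#' @export
make_dataset <- function(sim) {
  topo <- generate_topology(sim)
  expr <- generate_expression(topo, sim)
  c(topo, expr, list(sim = sim))
}

#' @rdname make_dataset
#' @export
make_null_dataset <- function(sim) {
  sim0 <- sim
  sim0$effect_size <- 0
  topo <- generate_topology(sim0)
  topo$truth$pairs$effect <- 0
  expr <- generate_expression(topo, sim0)
  c(topo, expr, list(sim = sim0))
}

#' Write a simulated dataset to plain-text files
#'
#' Writes the three expression TSVs (features x samples), the site
#' table, the annotation and the ground-truth tables into a directory.
#'
#' @param dataset A bundle from [make_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr_expr <- function(em, name) {
    df <- data.frame(feature_id = feature_ids(em), t(em$values),
                     check.names = FALSE)
    data.table::fwrite(df, file.path(dir, name), sep = "\t")
  }
  wr_expr(dataset$mirna, "expression_mirna.tsv")
  wr_expr(dataset$transcript, "expression_transcript.tsv")
  wr_expr(dataset$gene, "expression_gene.tsv")
  data.table::fwrite(dataset$sites, file.path(dir, "sites.tsv"), sep = "\t")
  data.table::fwrite(dataset$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t")
  data.table::fwrite(dataset$truth$pairs, file.path(dir, "truth_pairs.tsv"),
                     sep = "\t")
  data.table::fwrite(dataset$truth$binding,
                     file.path(dir, "truth_binding.tsv"), sep = "\t")
  invisible(dir)
}
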