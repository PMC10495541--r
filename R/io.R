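#' Read a target-site prediction table
#'
#' Parses a TarPmiR-style delimited table of predicted miRNA binding sites
#' on transcripts. The reader looks for columns named (case-insensitively)
#' miRNA/mirna_id, transcript/mRNA/transcript_id, start/beginning,
#' end/site_end and probability/binding_probability; any further columns
#' are ignored. Coordinates are normalized to 0-based half-open transcript
#' coordinates; set `coords = "one_based_inclusive"` for tools that emit
#' 1-based inclusive positions.
#'
#' @param path Path to the table.
#' @param prob_floor Records with probability strictly below this are
#'   dropped (default 0.5, the usual lower reporting bound of the
#'   predictor output).
#' @param coords Coordinate convention of the input file.
#' @return A data.frame with columns `mirna_id`, `transcript_id`, `start`,
#'   `end` (0-based half-open), `probability`.
#' @export
read_site_predictions <- function(path, prob_floor = 0.5,
                                  coords = c("zero_half_open",
                                             "one_based_inclusive")) {
  coords <- match.arg(coords)
  if (!file.exists(path)) stop("site prediction file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  pick <- function(cands, what) {
    hit <- which(tolower(colnames(dt)) %in% cands)
    if (!length(hit)) stop("site table lacks a ", what, " column: ", path)
    hit[1L]
  }
  i_m <- pick(c("mirna", "mirna_id", "miRNA"), "miRNA id")
  i_t <- pick(c("transcript", "transcript_id", "mrna", "mrna_id"), "transcript id")
  i_s <- pick(c("start", "beginning", "site_start"), "start")
  i_e <- pick(c("end", "site_end"), "end")
  i_p <- pick(c("probability", "binding_probability", "prob"), "probability")
  out <- data.frame(
    mirna_id = as.character(dt[[i_m]]),
    transcript_id = as.character(dt[[i_t]]),
    start = as.integer(dt[[i_s]]),
    end = as.integer(dt[[i_e]]),
    probability = as.numeric(dt[[i_p]]),
    stringsAsFactors = FALSE
  )
  if (coords == "one_based_inclusive") {
    out$start <- out$start - 1L
  }
  bad <- which(out$probability < 0 | out$probability > 1 | is.na(out$probability))
  if (length(bad)) {
    stop(sprintf("probability outside [0,1] for site %s/%s (row %d): %s",
                 out$mirna_id[bad[1L]], out$transcript_id[bad[1L]], bad[1L],
                 out$probability[bad[1L]]))
  }
  bad <- which(is.na(out$start) | is.na(out$end) | out$start < 0 |
                 out$end <= out$start)
  if (length(bad)) {
    stop(sprintf("invalid coordinates for site %s/%s (row %d): [%s, %s)",
                 out$mirna_id[bad[1L]], out$transcript_id[bad[1L]], bad[1L],
                 out$start[bad[1L]], out$end[bad[1L]]))
  }
  n0 <- nrow(out)
  out <- out[out$probability >= prob_floor, , drop = FALSE]
  rownames(out) <- NULL
  sm_log("read %d sites from %s (%d below probability floor %.2f dropped)",
         n0, path, n0 - nrow(out), prob_floor)
  out
}

#' Read transcript annotation
#'
#' Accepts either a 5-column TSV with header
#' `transcript_id, gene_id, length, cds_start, cds_end` (transcript
#' coordinates, 0-based half-open) or a GTF with `exon` and `CDS`
#' features, from which the transcript-coordinate CDS is computed by
#' summing exon lengths 5' to 3' (strand-aware). Transcripts without a
#' CDS are skipped with a logged count; coding-region analysis has no use
#' for them.
#'
#' @param path Path to the TSV or GTF file (`.gtf`/`.gff` extension, or
#'   `format = "gtf"`).
#' @param format `"auto"` (by extension), `"tsv"` or `"gtf"`.
#' @return A data.frame with columns `transcript_id`, `gene_id`, `length`,
#'   `cds_start`, `cds_end`; attribute `n_skipped_no_cds` carries the
#'   number of CDS-less transcripts dropped.
#' @export
read_transcript_annotation <- function(path, format = c("auto", "tsv", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff|gff3)(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "tsv"
  }
  if (format == "gtf") return(read_annotation_gtf(path))

  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("transcript_id", "gene_id", "length", "cds_start", "cds_end")
  if (!all(need %in% colnames(dt))) {
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  }
  ann <- data.frame(
    transcript_id = as.character(dt$transcript_id),
    gene_id = as.character(dt$gene_id),
    length = as.integer(dt$length),
    cds_start = as.integer(dt$cds_start),
    cds_end = as.integer(dt$cds_end),
    stringsAsFactors = FALSE
  )
  attr(ann, "n_skipped_no_cds") <- 0L
  validate_annotation(ann, path)
}

validate_annotation <- function(ann, path = "<annotation>") {
  dup <- unique(ann$transcript_id[duplicated(ann$transcript_id)])
  if (length(dup)) stop("duplicated transcript id(s): ", paste(dup, collapse = ", "))
  bad <- which(is.na(ann$gene_id) | ann$gene_id == "")
  if (length(bad)) {
    stop("transcript without gene: ", ann$transcript_id[bad[1L]], " in ", path)
  }
  bad <- which(!(ann$length > 0) | is.na(ann$length))
  if (length(bad)) stop("non-positive length for transcript ", ann$transcript_id[bad[1L]])
  bad <- which(ann$cds_start < 0 | ann$cds_end > ann$length |
                 ann$cds_start >= ann$cds_end)
  if (length(bad)) {
    stop(sprintf("invalid CDS [%d, %d) for transcript %s (length %d)",
                 ann$cds_start[bad[1L]], ann$cds_end[bad[1L]],
                 ann$transcript_id[bad[1L]], ann$length[bad[1L]]))
  }
  ann
}

# GTF branch: exon features give transcript length and the genomic->
# transcript coordinate map; CDS features are projected through it.
read_annotation_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GTF requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  md <- as.data.frame(gr)
  if (!all(c("type", "transcript_id") %in% colnames(md))) {
    stop("GTF lacks type/transcript_id attributes: ", path)
  }
  ex <- md[md$type == "exon", , drop = FALSE]
  cds <- md[md$type == "CDS", , drop = FALSE]
  if (!nrow(ex)) stop("GTF contains no exon features: ", path)
  tx_ids <- unique(ex$transcript_id)
  rows <- vector("list", length(tx_ids))
  skipped <- 0L
  for (i in seq_along(tx_ids)) {
    tid <- tx_ids[i]
    e <- ex[ex$transcript_id == tid, , drop = FALSE]
    strand <- as.character(e$strand[1L])
    # transcript order: ascending genomic start on +, descending on -
    e <- e[order(e$start, decreasing = identical(strand, "-")), , drop = FALSE]
    tx_len <- sum(e$end - e$start + 1L)
    cc <- cds[cds$transcript_id == tid, , drop = FALSE]
    if (!nrow(cc)) {
      skipped <- skipped + 1L
      next
    }
    offset <- 0L
    seg_lo <- integer(0)
    seg_hi <- integer(0)
    for (k in seq_len(nrow(e))) {
      ov <- cc[cc$start <= e$end[k] & cc$end >= e$start[k], , drop = FALSE]
      if (nrow(ov)) {
        for (q in seq_len(nrow(ov))) {
          s <- max(ov$start[q], e$start[k])
          t <- min(ov$end[q], e$end[k])
          lo <- if (identical(strand, "-")) offset + (e$end[k] - t)
                else offset + (s - e$start[k])
          seg_lo <- c(seg_lo, lo)
          seg_hi <- c(seg_hi, lo + (t - s + 1L))
        }
      }
      offset <- offset + (e$end[k] - e$start[k] + 1L)
    }
    gene <- if ("gene_id" %in% colnames(e)) as.character(e$gene_id[1L]) else NA_character_
    rows[[i]] <- data.frame(
      transcript_id = tid, gene_id = gene, length = tx_len,
      cds_start = min(seg_lo), cds_end = max(seg_hi),
      stringsAsFactors = FALSE
    )
  }
  ann <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(ann) || !nrow(ann)) stop("no transcript with a CDS in ", path)
  rownames(ann) <- NULL
  sm_log("annotation %s: %d transcripts with CDS, %d without CDS skipped",
         path, nrow(ann), skipped)
  attr(ann, "n_skipped_no_cds") <- skipped
  validate_annotation(ann, path)
}

# Column order of the per-pair results table.
results_columns <- function() {
  c("mirna", "gene", "setting", "k", "l", "rmse_full", "rmse_reduced",
    "lrt_stat", "df", "p", "p_adj", "adj_r2_full", "adj_r2_reduced",
    "cohens_f2")
}

#' Write / read the per-pair model results table
#'
#' Plain TSV with one row per (miRNA, gene, setting): transcript counts
#' `k` (no sites in the investigated region) and `l` (with sites),
#' test-set RMSEs, the likelihood-ratio statistic and its degrees of
#' freedom, raw and BH-adjusted p-values, adjusted R-squared of both fits
#' and Cohen's f2. Numbers round-trip to at least 12 significant digits.
#'
#' @param results Data.frame carrying at least the columns returned by
#'   `splicemir:::results_columns()`; extra columns are dropped on write.
#' @param path Output path.
#' @return `write_results_table()` returns `path` invisibly;
#'   `read_results_table()` returns the data.frame.
#' @export
write_results_table <- function(results, path) {
  cols <- results_columns()
  if (is.null(results) || nrow(as.data.frame(results)) == 0L) {
    empty <- stats::setNames(
      as.data.frame(rep(list(numeric(0)), length(cols))), cols)
    data.table::fwrite(empty, path, sep = "\t")
    return(invisible(path))
  }
  results <- as.data.frame(results)
  missing <- setdiff(cols, colnames(results))
  if (length(missing)) {
    stop("results lack column(s): ", paste(missing, collapse = ", "))
  }
  data.table::fwrite(results[, cols, drop = FALSE], path, sep = "\t")
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE, sep = "\t")
  missing <- setdiff(results_columns(), colnames(dt))
  if (length(missing)) {
    stop("results table lacks column(s): ", paste(missing, collapse = ", "))
  }
  dt
}
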