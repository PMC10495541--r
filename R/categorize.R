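#' Locate a target site relative to the coding region
#'
#' Determines which region(s) of a transcript a predicted site overlaps:
#' the coding sequence, the non-coding flanks (5'UTR and 3'UTR, treated
#' jointly as "noncoding"), or both when the site straddles a CDS
#' boundary. All intervals are 0-based half-open in transcript
#' coordinates.
#'
#' @param site One-row data.frame (or list) with `start`, `end` and
#'   `transcript_id` as produced by [read_site_predictions()].
#' @param transcript One-row data.frame (or list) with `transcript_id`,
#'   `length`, `cds_start`, `cds_end`.
#' @return Character vector: subset of `c("coding", "noncoding")`,
#'   never empty.
#' @export
#' @examples
#' tm <- list(transcript_id = "t1", length = 1000L,
#'            cds_start = 100L, cds_end = 700L)
#' classify_site_region(list(transcript_id = "t1", start = 95, end = 105), tm)
classify_site_region <- function(site, transcript) {
  if (!is.null(site$transcript_id) &&
      !identical(as.character(site$transcript_id),
                 as.character(transcript$transcript_id))) {
    stop("site and transcript ids differ: ", site$transcript_id, " vs ",
         transcript$transcript_id)
  }
  s <- as.integer(site$start); e <- as.integer(site$end)
  if (e > transcript$length) {
    stop(sprintf("site [%d, %d) extends beyond transcript %s (length %d)",
                 s, e, transcript$transcript_id, transcript$length))
  }
  out <- character(0)
  if (s < transcript$cds_end && e > transcript$cds_start) out <- c(out, "coding")
  if (s < transcript$cds_start || e > transcript$cds_end) out <- c(out, "noncoding")
  out
}

category_levels <- function() {
  c("NON_BINDING", "CODING_ONLY", "NONCODING_ONLY", "BOTH", "DISCARD")
}

#' Classify one (miRNA, transcript) pair by its predicted sites
#'
#' Binding classification used throughout the analysis:
#' `NON_BINDING` if no site exceeds the low probability cutoff;
#' `DISCARD` if some site exceeds the low cutoff but none the high cutoff
#' (only intermediate-confidence evidence -- treated as noise);
#' otherwise the union of regions hit by high-confidence sites decides
#' `CODING_ONLY`, `NONCODING_ONLY` or `BOTH`. Sub-threshold sites on a
#' transcript that also carries a high-confidence site do not affect the
#' class.
#'
#' @param sites Data.frame of sites for this (miRNA, transcript); may be
#'   empty. All rows must refer to `transcript$transcript_id`.
#' @param transcript One-row annotation record (see
#'   [classify_site_region()]).
#' @param cfg A [pipeline_config()] supplying the 0.5/0.8 cutoffs.
#' @return One of `"NON_BINDING"`, `"CODING_ONLY"`, `"NONCODING_ONLY"`,
#'   `"BOTH"`, `"DISCARD"`.
#' @export
categorize_transcript <- function(sites, transcript, cfg = pipeline_config()) {
  if (is.null(sites) || nrow(sites) == 0L) return("NON_BINDING")
  if (!all(as.character(sites$transcript_id) ==
             as.character(transcript$transcript_id))) {
    stop("sites for a different transcript passed to categorize_transcript")
  }
  if (!any(sites$probability > cfg$bind_prob_low)) return("NON_BINDING")
  high <- sites[sites$probability > cfg$bind_prob_high, , drop = FALSE]
  if (nrow(high) == 0L) return("DISCARD")
  regions <- unique(unlist(lapply(seq_len(nrow(high)), function(i) {
    classify_site_region(high[i, ], transcript)
  })))
  if (all(c("coding", "noncoding") %in% regions)) return("BOTH")
  if ("coding" %in% regions) return("CODING_ONLY")
  "NONCODING_ONLY"
}

#' Categorize every (miRNA, transcript) pair in a site table
#'
#' Vectorized application of [categorize_transcript()] over a full site
#' table. Pairs absent from the table are implicitly `NON_BINDING` and
#' are not materialized. Sites on transcripts missing from the annotation
#' are dropped with a logged count.
#'
#' @param sites Site table from [read_site_predictions()].
#' @param annotation Annotation from [read_transcript_annotation()].
#' @param cfg A [pipeline_config()].
#' @return Data.frame with columns `mirna_id`, `transcript_id`,
#'   `category`.
#' @export
categorize_sites <- function(sites, annotation, cfg = pipeline_config()) {
  known <- sites$transcript_id %in% annotation$transcript_id
  if (any(!known)) {
    sm_log("%d sites on transcripts absent from the annotation dropped",
           sum(!known))
    sites <- sites[known, , drop = FALSE]
  }
  if (nrow(sites) == 0L) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      category = character(0), stringsAsFactors = FALSE))
  }
  dt <- data.table::as.data.table(sites)
  ann <- data.table::as.data.table(
    annotation[, c("transcript_id", "length", "cds_start", "cds_end")])
  dt <- merge(dt, ann, by = "transcript_id", sort = FALSE)
  if (any(dt$end > dt$length)) {
    bad <- which(dt$end > dt$length)[1L]
    stop(sprintf("site [%d, %d) extends beyond transcript %s (length %d)",
                 dt$start[bad], dt$end[bad], dt$transcript_id[bad],
                 dt$length[bad]))
  }
  dt[, `:=`(
    in_coding = start < cds_end & end > cds_start,
    in_noncoding = start < cds_start | end > cds_end
  )]
  hi <- cfg$bind_prob_high; lo <- cfg$bind_prob_low
  res <- dt[, {
    if (!any(probability > lo)) {
      cat_ <- "NON_BINDING"
    } else {
      h <- probability > hi
      if (!any(h)) {
        cat_ <- "DISCARD"
      } else {
        cod <- any(in_coding[h]); noc <- any(in_noncoding[h])
        cat_ <- if (cod && noc) "BOTH" else if (cod) "CODING_ONLY" else "NONCODING_ONLY"
      }
    }
    list(category = cat_)
  }, by = .(mirna_id, transcript_id)]
  out <- as.data.frame(res)
  out$mirna_id <- as.character(out$mirna_id)
  out$transcript_id <- as.character(out$transcript_id)
  out
}

#' Assemble full/reduced transcript sets per miRNA-gene pair
#'
#' Builds, for one analysis setting, the nested transcript universes of
#' every eligible miRNA-gene pair:
#' \describe{
#'   \item{ALLT}{full = all transcripts (any binding class plus
#'     non-binding), reduced = non-binding transcripts.}
#'   \item{TNBN}{full = non-binding transcripts plus transcripts binding
#'     only in the coding region, reduced = non-binding transcripts.}
#'   \item{TBN}{full = transcripts binding in non-coding regions
#'     (with or without additional coding sites), reduced = transcripts
#'     binding only in non-coding regions.}
#' }
#' Discarded transcripts (intermediate-confidence sites only) appear in
#' no set. Pairs whose reduced set is empty or equals the full set are
#' omitted: they admit no nested comparison.
#'
#' @param categories Output of [categorize_sites()] (pairs not listed are
#'   non-binding).
#' @param annotation Annotation data.frame; every categorized transcript
#'   must appear here.
#' @param setting `"ALLT"`, `"TNBN"` or `"TBN"`.
#' @param cfg A [pipeline_config()].
#' @return List of pair universes; each element is a list with
#'   `mirna_id`, `gene_id`, `setting`, `full` and `reduced` (character
#'   vectors of transcript ids, `reduced` a strict subset of `full`).
#' @export
build_pair_universe <- function(categories, annotation,
                                setting = c("ALLT", "TNBN", "TBN"),
                                cfg = pipeline_config()) {
  setting <- match.arg(setting)
  miss <- setdiff(categories$transcript_id, annotation$transcript_id)
  if (length(miss)) {
    stop("categorized transcript(s) missing from annotation: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  gene_of <- stats::setNames(annotation$gene_id, annotation$transcript_id)
  tx_of_gene <- split(annotation$transcript_id, annotation$gene_id)

  cat_dt <- data.table::as.data.table(categories)
  cat_dt[, gene_id := gene_of[transcript_id]]
  # settings differ in which class counts as "binding in the investigated
  # region" (goes to full only) vs "not binding there" (goes to reduced)
  sets <- switch(setting,
    ALLT = list(binding = c("CODING_ONLY", "NONCODING_ONLY", "BOTH"),
                escape = "NON_BINDING"),
    TNBN = list(binding = "CODING_ONLY", escape = "NON_BINDING"),
    TBN  = list(binding = "BOTH", escape = "NONCODING_ONLY")
  )
  cand <- unique(cat_dt[category %in% sets$binding, .(mirna_id, gene_id)])
  out <- vector("list", nrow(cand))
  n_kept <- 0L
  if (nrow(cand)) {
    key <- paste(cat_dt$mirna_id, cat_dt$transcript_id, sep = "\r")
    cat_lookup <- stats::setNames(cat_dt$category, key)
    for (i in seq_len(nrow(cand))) {
      m <- cand$mirna_id[i]; g <- cand$gene_id[i]
      txs <- tx_of_gene[[g]]
      cats <- cat_lookup[paste(m, txs, sep = "\r")]
      cats[is.na(cats)] <- "NON_BINDING"
      binding <- txs[cats %in% sets$binding]
      escape <- txs[cats %in% sets$escape]
      if (length(binding) == 0L || length(escape) == 0L) next
      n_kept <- n_kept + 1L
      out[[n_kept]] <- pair_universe(m, g, setting,
                                     full = c(escape, binding),
                                     reduced = escape)
    }
  }
  out[seq_len(n_kept)]
}

#' @rdname build_pair_universe
#' @param mirna_id,gene_id Identifiers of the pair.
#' @param full,reduced Character vectors of transcript ids with
#'   `reduced` a strict non-empty subset of `full`.
#' @export
pair_universe <- function(mirna_id, gene_id, setting, full, reduced) {
  full <- as.character(full); reduced <- as.character(reduced)
  if (!length(full)) stop("empty full transcript set for ", mirna_id, "/", gene_id)
  if (anyDuplicated(full)) stop("duplicated transcripts in full set")
  if (!length(reduced) || !all(reduced %in% full) ||
        length(reduced) >= length(full)) {
    stop(sprintf("reduced set must be a strict non-empty subset of full (%s/%s)",
                 mirna_id, gene_id))
  }
  structure(list(mirna_id = as.character(mirna_id),
                 gene_id = as.character(gene_id),
                 setting = setting, full = full, reduced = reduced),
            class = "pair_universe")
}

#' @export
print.pair_universe <- function(x, ...) {
  cat(sprintf("pair_universe %s ~ %s [%s]: full {%s}, reduced {%s}\n",
              x$mirna_id, x$gene_id, x$setting,
              paste(x$full, collapse = ", "),
              paste(x$reduced, collapse = ", ")))
  invisible(x)
}

#' Dump the category table for audit
#'
#' @param categories Output of [categorize_sites()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_category_table <- function(categories, path) {
  data.table::fwrite(categories, path, sep = "\t")
  invisible(path)
}
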