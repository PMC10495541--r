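#' Construct an expression matrix
#'
#' A thin validated container for log2-scale abundances: a numeric
#' samples x features matrix with unique dimnames, a `kind` tag and the
#' floor value that represents "not expressed" (values at the floor are
#' permitted; the floor marks absence, it is not a lower bound).
#'
#' @param values Numeric matrix, samples in rows, features in columns,
#'   both with unique names; all values finite.
#' @param kind One of `"mirna"`, `"transcript"`, `"gene"`.
#' @param floor Log2 value marking "not expressed" (default `log2(0.001)`).
#' @return An object of class `"expression_matrix"`.
#' @export
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("s1", "s2"), c("f1", "f2", "f3")))
#' em <- expression_matrix(m, "gene")
#' feature_ids(em)
expression_matrix <- function(values, kind = c("mirna", "transcript", "gene"),
                              floor = log2(0.001)) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry sample (row) and feature (column) names")
  }
  dup_s <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_s)) stop("duplicated sample id(s): ", paste(dup_s, collapse = ", "))
  dup_f <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_f)) stop("duplicated feature id(s): ", paste(dup_f, collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at sample '%s', feature '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  stopifnot(is.numeric(floor), length(floor) == 1L, is.finite(floor))
  structure(list(kind = kind, values = values, floor = floor),
            class = "expression_matrix")
}

#' @rdname expression_matrix
#' @param x An `"expression_matrix"`.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
feature_ids <- function(x) colnames(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d samples x %d features, floor %.4g\n",
              x$kind, nrow(x$values), ncol(x$values), x$floor))
  invisible(x)
}

# Subset by sample and/or feature ids, preserving the requested order.
em_subset <- function(x, samples = NULL, features = NULL) {
  v <- x$values
  if (!is.null(samples)) {
    miss <- setdiff(samples, rownames(v))
    if (length(miss)) stop("unknown sample id(s): ", paste(utils::head(miss, 5), collapse = ", "))
    v <- v[samples, , drop = FALSE]
  }
  if (!is.null(features)) {
    miss <- setdiff(features, colnames(v))
    if (length(miss)) stop("unknown feature id(s): ", paste(utils::head(miss, 5), collapse = ", "))
    v <- v[, features, drop = FALSE]
  }
  expression_matrix(v, x$kind, x$floor)
}

#' Read a delimited expression table
#'
#' Expects a delimited text table (gz accepted) whose first column holds
#' feature ids and whose header holds sample ids; set
#' `features_in_rows = FALSE` for the transposed orientation (first column
#' sample ids, header feature ids). Malformed input is rejected, never
#' coerced: missing or non-numeric cells and duplicated ids are errors
#' naming the offending record.
#'
#' @param path Path to the table.
#' @param kind One of `"mirna"`, `"transcript"`, `"gene"`.
#' @param floor Log2 value marking absence (default `log2(0.001)`).
#' @param features_in_rows `TRUE` (default) if rows are features.
#' @param rescale_rpm If `TRUE`, values arriving as log2(rpm + 1) are
#'   rescaled to the log2(rpm + 0.001) convention used throughout, i.e.
#'   v -> log2(2^v - 1 + 0.001).
#' @return An `"expression_matrix"` (samples x features).
#' @export
read_expression_table <- function(path, kind, floor = log2(0.001),
                                  features_in_rows = TRUE,
                                  rescale_rpm = FALSE) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          na.strings = "NA")
  if (ncol(dt) < 2L) stop("expression table needs an id column plus data: ", path)
  ids <- as.character(dt[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("duplicated %s id(s) in %s: %s",
                 if (features_in_rows) "feature" else "sample",
                 path, paste(dup, collapse = ", ")))
  }
  cols <- colnames(dt)[-1L]
  dupc <- unique(cols[duplicated(cols)])
  if (length(dupc)) {
    stop(sprintf("duplicated %s id(s) in %s: %s",
                 if (features_in_rows) "sample" else "feature",
                 path, paste(dupc, collapse = ", ")))
  }
  for (j in seq_along(cols)) {
    col <- dt[[j + 1L]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
      stop(sprintf("non-numeric cell in %s at row '%s', column '%s'",
                   path, ids[bad], cols[j]))
    }
    if (anyNA(col)) {
      bad <- which(is.na(col))[1L]
      stop(sprintf("missing value in %s at row '%s', column '%s'",
                   path, ids[bad], cols[j]))
    }
  }
  mat <- as.matrix(dt[, -1L, drop = FALSE])
  rownames(mat) <- ids
  if (features_in_rows) mat <- t(mat)
  if (rescale_rpm) mat <- log2(2^mat - 1 + 0.001)
  expression_matrix(mat, kind = kind, floor = floor)
}
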