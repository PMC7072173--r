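GISTIC_CODES <- -2L:2L

#' Internal stage-tagged logger
#'
#' Writes machine-parseable lines of the form `[stage] LEVEL: msg` to stderr.
#' Verbosity is controlled by `options(snohost.log_level = ...)` with levels
#' "debug" < "info" < "warn" < "quiet".
#' @noRd
sno_log <- function(stage, msg, level = "info") {
  levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  thr <- levels[[getOption("snohost.log_level", "info")]]
  if (levels[[level]] >= thr && level != "quiet") {
    message(sprintf("[%s] %s: %s", stage, toupper(level), msg))
  }
  invisible(NULL)
}

#' Construct a discrete copy-number matrix
#'
#' A `cna_matrix` holds GISTIC-style discrete copy-number codes for a set of
#' genes (rows) across samples (columns). Valid codes are -2 (deep deletion),
#' -1 (shallow deletion), 0 (diploid), 1 (gain) and 2 (high-level
#' amplification); `NA` marks a missing call.
#'
#' @param codes integer matrix, genes x samples, cells in \{-2,...,2\} or NA.
#' @param gene_ids character vector of unique gene identifiers (rownames).
#' @param sample_ids character vector of unique sample identifiers (colnames).
#' @param gene_symbols optional character vector of display symbols, parallel
#'   to `gene_ids`.
#' @return an object of class `cna_matrix` (an integer matrix with dimnames
#'   and an optional `gene_symbols` attribute).
#' @export
cna_matrix <- function(codes, gene_ids = rownames(codes),
                       sample_ids = colnames(codes), gene_symbols = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  validate_ids(gene_ids, sample_ids, dim(codes))
  bad <- !is.na(codes) & !(codes %in% GISTIC_CODES)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid copy-number code %s at gene '%s', sample '%s'",
                 codes[bad][1L], gene_ids[idx[1L]], sample_ids[idx[2L]]))
  }
  dimnames(codes) <- list(gene_ids, sample_ids)
  if (!is.null(gene_symbols)) {
    stopifnot(length(gene_symbols) == length(gene_ids))
    attr(codes, "gene_symbols") <- stats::setNames(as.character(gene_symbols), gene_ids)
  }
  class(codes) <- c("cna_matrix", class(codes))
  codes
}

#' Construct an expression matrix
#'
#' Holds non-negative RSEM-style abundances for genes (rows) across samples
#' (columns); `NA` marks a missing value.
#'
#' @inheritParams cna_matrix
#' @param values numeric matrix, genes x samples, cells >= 0 or NA.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, gene_ids = rownames(values),
                        sample_ids = colnames(values), gene_symbols = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  validate_ids(gene_ids, sample_ids, dim(values))
  bad <- !is.na(values) & values < 0
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative expression value %g at gene '%s', sample '%s'",
                 values[bad][1L], gene_ids[idx[1L]], sample_ids[idx[2L]]))
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  if (!is.null(gene_symbols)) {
    stopifnot(length(gene_symbols) == length(gene_ids))
    attr(values, "gene_symbols") <- stats::setNames(as.character(gene_symbols), gene_ids)
  }
  class(values) <- c("expr_matrix", class(values))
  values
}

validate_ids <- function(gene_ids, sample_ids, dims) {
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene_ids and sample_ids are required")
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (length(gene_ids) != dims[1L] || length(sample_ids) != dims[2L]) {
    stop("matrix dimensions do not match id lists")
  }
  invisible(TRUE)
}

#' Bundle matrices of one tumor cohort
#'
#' @param acronym short cohort label (e.g. a TCGA-style acronym).
#' @param cna a [cna_matrix()].
#' @param expr optional [expr_matrix()]; when present, `n_samples` counts the
#'   samples shared by both matrices.
#' @return an object of class `cohort` with elements `acronym`, `cna`, `expr`
#'   and `n_samples`.
#' @export
cohort <- function(acronym, cna, expr = NULL) {
  stopifnot(is.character(acronym), nzchar(acronym), inherits(cna, "cna_matrix"))
  if (!is.null(expr) && !inherits(expr, "expr_matrix")) {
    stop("expr must be an expr_matrix")
  }
  n_samples <- if (is.null(expr)) ncol(cna) else {
    length(intersect(colnames(cna), colnames(expr)))
  }
  structure(list(acronym = acronym, cna = cna, expr = expr,
                 n_samples = n_samples),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort %s> %d genes x %d samples (CNA)%s\n",
              x$acronym, nrow(x$cna), ncol(x$cna),
              if (is.null(x$expr)) "" else sprintf(", expression %d x %d",
                                                  nrow(x$expr), ncol(x$expr))))
  invisible(x)
}

# Shared reader for the two matrix dialects. First column must be `gene_id`;
# an optional second column `gene_symbol` carries display names; every other
# column is one sample. Empty string and "NA" are missing.
read_gene_matrix <- function(path, kind = c("cna", "expr")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA"), quote = "",
                           comment.char = "")
  cols <- colnames(raw)
  if (length(cols) < 2L || cols[1L] != "gene_id") {
    stop("malformed header: first column must be 'gene_id'")
  }
  has_symbol <- length(cols) >= 2L && cols[2L] == "gene_symbol"
  sample_cols <- if (has_symbol) cols[-(1:2)] else cols[-1L]
  if (length(sample_cols) == 0L) stop("malformed header: no sample columns")
  if (anyDuplicated(sample_cols)) {
    stop(sprintf("duplicate sample columns: %s",
                 paste(unique(sample_cols[duplicated(sample_cols)]), collapse = ", ")))
  }
  gene_ids <- raw$gene_id
  keep <- !is.na(gene_ids) & nzchar(trimws(gene_ids))
  if (any(!keep)) {
    sno_log("io", sprintf("dropped %d row(s) with unparseable gene id", sum(!keep)),
            "warn")
    raw <- raw[keep, , drop = FALSE]
    gene_ids <- gene_ids[keep]
  }
  dup <- duplicated(gene_ids)
  if (any(dup)) {
    warning(sprintf("duplicate gene id(s) dropped (later rows): %s",
                    paste(unique(gene_ids[dup]), collapse = ", ")))
    raw <- raw[!dup, , drop = FALSE]
    gene_ids <- gene_ids[!dup]
  }
  if (nrow(raw) == 0L) stop("no parseable gene rows")
  cell_chr <- as.matrix(raw[, sample_cols, drop = FALSE])
  cells <- suppressWarnings(as.numeric(cell_chr))
  unparseable <- !is.na(cell_chr) & is.na(cells)
  if (any(unparseable)) {
    idx <- which(matrix(unparseable, nrow = nrow(raw)), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell '%s' at gene '%s', sample '%s'",
                 cell_chr[unparseable][1L], gene_ids[idx[1L]], sample_cols[idx[2L]]))
  }
  cells <- matrix(cells, nrow = nrow(raw),
                  dimnames = list(gene_ids, sample_cols))
  symbols <- if (has_symbol) raw$gene_symbol else NULL
  if (kind == "cna") {
    non_int <- !is.na(cells) & cells != round(cells)
    if (any(non_int)) {
      idx <- which(non_int, arr.ind = TRUE)[1L, ]
      stop(sprintf("non-integer copy-number code '%s' at gene '%s', sample '%s'",
                   cells[non_int][1L], gene_ids[idx[1L]], sample_cols[idx[2L]]))
    }
    cna_matrix(cells, gene_ids, sample_cols, gene_symbols = symbols)
  } else {
    expr_matrix(cells, gene_ids, sample_cols, gene_symbols = symbols)
  }
}

#' Read a discrete copy-number matrix from TSV
#'
#' Expects a cBioPortal `data_CNA`-like dialect: a `gene_id` column
#' (Ensembl-style identifiers), an optional `gene_symbol` column, then one
#' column per sample with codes in \{-2,-1,0,1,2\}. Empty cells and "NA" are
#' treated as missing. Rows without a gene id are dropped with a log line;
#' for duplicated gene ids only the first row is kept (with a warning). Any
#' out-of-range or non-integer code is a hard error naming the offending
#' gene/sample cell; duplicate sample columns are a hard error.
#'
#' @param path path to a tab-separated file.
#' @return a [cna_matrix()].
#' @export
read_cna_matrix <- function(path) read_gene_matrix(path, "cna")

#' Read an expression matrix from TSV
#'
#' Same dialect as [read_cna_matrix()], but cells are non-negative reals
#' (RSEM-style abundances); a negative cell is a hard error.
#'
#' @param path path to a tab-separated file.
#' @return an [expr_matrix()].
#' @export
read_expr_matrix <- function(path) read_gene_matrix(path, "expr")

#' Write a result table as TSV
#'
#' Writes a data frame as UTF-8 tab-separated text with a header line and no
#' row-name column. Numeric columns are written with 15 significant digits so
#' round-trips preserve doubles to well below 1e-9 relative error.
#'
#' @param rows a data frame.
#' @param path output path.
#' @param schema optional character vector of required column names; a
#'   mismatch is an error.
#' @export
write_table <- function(rows, path, schema = NULL) {
  stopifnot(is.data.frame(rows))
  if (!is.null(schema) && !identical(colnames(rows), schema)) {
    stop(sprintf("table columns (%s) do not match schema (%s)",
                 paste(colnames(rows), collapse = ","),
                 paste(schema, collapse = ",")))
  }
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- out[[j]]
      s <- vapply(v, function(x) {
        if (is.na(x)) NA_character_ else format(x, digits = 15, scientific = FALSE)
      }, character(1L))
      out[[j]] <- s
    }
  }
  utf8 <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(utf8))
  utils::write.table(out, utf8, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(NULL)
}

# Serialize a gene x samples matrix back to the TSV dialect read_* consumes.
write_gene_matrix <- function(mat, path) {
  symbols <- attr(mat, "gene_symbols")
  df <- data.frame(gene_id = rownames(mat), stringsAsFactors = FALSE)
  if (!is.null(symbols)) df$gene_symbol <- unname(symbols[rownames(mat)])
  body <- as.data.frame(unclass(mat)[, , drop = FALSE], check.names = FALSE,
                        stringsAsFactors = FALSE)
  rownames(body) <- NULL
  write_table(cbind(df, body), path)
}

#' Write a copy-number matrix as TSV
#' @param cna a [cna_matrix()].
#' @param path output path.
#' @export
write_cna_matrix <- function(cna, path) write_gene_matrix(cna, path)

#' Write an expression matrix as TSV
#' @param expr an [expr_matrix()].
#' @param path output path.
#' @export
write_expr_matrix <- function(expr, path) write_gene_matrix(expr, path)
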