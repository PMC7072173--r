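#' Diploid-referenced expression Z-scores
#'
#' Standardizes each gene's expression against the samples that are diploid
#' (copy-number code 0) for that gene: z = (x - mean_ref) / sd_ref, with the
#' unbiased (n-1) standard deviation. Genes whose diploid reference has
#' fewer than `min_ref` samples, or zero spread, get all cells flagged
#' undefined. Only samples present in both matrices are used, both for the
#' reference and for the scores, so that copy-number and expression calls
#' stay comparable downstream; samples with a missing copy-number code do
#' not enter the reference even when expression is available.
#'
#' @param expr an [expr_matrix()].
#' @param cna a [cna_matrix()] sharing genes/samples with `expr`.
#' @param min_ref minimum number of diploid reference samples (default 3).
#' @return object of class `zscore_matrix`: list with `z` (gene x sample
#'   matrix, NA where undefined), `reference_n` (per-gene reference size) and
#'   `undefined_genes` (logical per gene).
#' @export
compute_z <- function(expr, cna, min_ref = 3L) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(cna, "cna_matrix"))
  genes <- intersect(rownames(expr), rownames(cna))
  samples <- intersect(colnames(expr), colnames(cna))
  if (length(samples) == 0L) stop("no overlapping samples between expression and CNA")
  if (length(genes) == 0L) stop("no overlapping genes between expression and CNA")
  x <- unclass(expr)[genes, samples, drop = FALSE]
  codes <- unclass(cna)[genes, samples, drop = FALSE]
  sno_syms <- attr(expr, "gene_symbols")
  if (!is.null(sno_syms) && any(grepl("^SNOR", sno_syms[genes]))) {
    sno_log("expression",
            "snoRNA rows present in the expression matrix; short-RNA library protocols may under-detect them",
            "info")
  }

  ref <- codes == 0L & !is.na(codes) & !is.na(x)
  xr <- x
  xr[!ref] <- NA
  ref_n <- rowSums(ref)
  mu <- rowMeans(xr, na.rm = TRUE)
  sq <- rowSums((xr - mu)^2, na.rm = TRUE)
  sdv <- ifelse(ref_n > 1L, sqrt(sq / (ref_n - 1L)), NA_real_)
  undef <- ref_n < min_ref | is.na(sdv) | sdv == 0
  if (any(undef)) {
    sno_log("expression", sprintf("%d gene(s) with undefined Z (reference < %d or zero spread)",
                                  sum(undef), min_ref), "warn")
  }
  z <- (x - mu) / sdv
  z[undef, ] <- NA_real_
  structure(list(z = z, reference_n = ref_n, undefined_genes = undef,
                 min_ref = as.integer(min_ref)),
            class = "zscore_matrix")
}

#' @export
print.zscore_matrix <- function(x, ...) {
  cat(sprintf("<zscore_matrix> %d genes x %d samples, %d gene(s) undefined\n",
              nrow(x$z), ncol(x$z), sum(x$undefined_genes)))
  invisible(x)
}

#' Call expression alteration from a Z-score
#'
#' `up` for z strictly greater than `up`, `down` for z strictly less than
#' `down`, `normal` otherwise; `undefined` where z itself is undefined.
#'
#' @param z numeric vector or matrix of Z-scores (NA = undefined), or a
#'   `zscore_matrix`.
#' @param up,down thresholds (defaults +2 / -2; strict inequalities).
#' @return character vector/matrix of calls in
#'   \{`up`, `down`, `normal`, `undefined`\}.
#' @export
classify_expression <- function(z, up = 2, down = -2) {
  if (inherits(z, "zscore_matrix")) z <- z$z
  out <- ifelse(is.na(z), "undefined",
                ifelse(z > up, "up", ifelse(z < down, "down", "normal")))
  if (is.matrix(z)) dimnames(out) <- dimnames(z)
  out
}

# Internal: per-couple call matrices for the aligned couples that have both
# members in the Z-score matrix. Returns NULL-padded character matrices.
couple_calls <- function(zcalls, aligned) {
  if (inherits(zcalls, "zscore_matrix")) zcalls <- classify_expression(zcalls)
  cpl <- aligned$couples
  have <- cpl$snorna_id %in% rownames(zcalls) & cpl$host_id %in% rownames(zcalls)
  cpl <- cpl[have, , drop = FALSE]
  if (nrow(cpl) == 0L) stop("no aligned couple has both members in the Z-score matrix")
  list(couples = cpl,
       sno = zcalls[cpl$snorna_id, , drop = FALSE],
       host = zcalls[cpl$host_id, , drop = FALSE])
}

#' Per-sample expression-alteration rates of a cohort
#'
#' Counts up- and down-calls over all (couple, sample) cells, split by
#' which member of the couple carries the call (snoRNA vs host gene), and
#' normalizes by the number of samples. Undefined calls are excluded from
#' the numerators and reported.
#'
#' @param zcalls a `zscore_matrix` or a call matrix from
#'   [classify_expression()].
#' @param aligned an `aligned_couples` object.
#' @param acronym cohort label for the output.
#' @return data frame with one row per (member, direction) holding counts
#'   and per-sample rates, with attribute `n_undefined_cells`.
#' @export
expression_rates <- function(zcalls, aligned, acronym = aligned$acronym) {
  cc <- couple_calls(zcalls, aligned)
  n_samples <- ncol(cc$sno)
  counts <- c(snorna_up = sum(cc$sno == "up"), snorna_down = sum(cc$sno == "down"),
              host_up = sum(cc$host == "up"), host_down = sum(cc$host == "down"))
  undef <- sum(cc$sno == "undefined") + sum(cc$host == "undefined")
  out <- data.frame(
    cohort = acronym,
    member = c("snorna", "snorna", "host", "host"),
    direction = c("up", "down", "up", "down"),
    n_events = as.integer(counts),
    n_samples = n_samples,
    rate_per_sample = as.numeric(counts) / n_samples,
    stringsAsFactors = FALSE)
  attr(out, "n_undefined_cells") <- undef
  attr(out, "n_couples") <- nrow(cc$couples)
  out
}

#' Top-k up-regulated couples of a cohort
#'
#' A couple is up-regulated in a sample if either member is called `up`
#' (a sample where both are up counts once); which member drove the call is
#' recorded. The denominator is the number of samples where at least one
#' member has a defined call. Ranking and tie-breaking follow
#' [top_k_couples()].
#'
#' @inheritParams expression_rates
#' @param k number of couples to return (default 10).
#' @return data frame with `rank`, couple identifiers, per-member counts,
#'   `up_sample_fraction` and a `members` flag
#'   (`snorna_only`/`host_only`/`both`/`none`).
#' @export
top_k_upregulated <- function(zcalls, aligned, k = 10L,
                              acronym = aligned$acronym) {
  stopifnot(k >= 1L)
  cc <- couple_calls(zcalls, aligned)
  sno_up <- cc$sno == "up"
  host_up <- cc$host == "up"
  defined <- cc$sno != "undefined" | cc$host != "undefined"
  up <- sno_up | host_up
  n_def <- rowSums(defined)
  n_up <- rowSums(up)
  n_sno <- rowSums(sno_up)
  n_host <- rowSums(host_up)
  members <- ifelse(n_sno > 0L & n_host > 0L, "both",
                    ifelse(n_sno > 0L, "snorna_only",
                           ifelse(n_host > 0L, "host_only", "none")))
  df <- data.frame(
    cohort = acronym, key = couple_key(cc$couples),
    label = couple_label(cc$couples),
    snorna_id = cc$couples$snorna_id, host_id = cc$couples$host_id,
    n_up = n_up, n_snorna_up = n_sno, n_host_up = n_host,
    n_defined = n_def,
    up_sample_fraction = ifelse(n_def > 0L, n_up / n_def, NA_real_),
    members = members, stringsAsFactors = FALSE)
  ord <- order(-df$up_sample_fraction, df$label, df$snorna_id, method = "radix")
  df <- utils::head(df[ord, , drop = FALSE], min(as.integer(k), nrow(df)))
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df[, c("rank", "cohort", "key", "label", "snorna_id", "host_id",
         "n_up", "n_snorna_up", "n_host_up", "n_defined",
         "up_sample_fraction", "members")]
}

#' Concordance between copy-number amplification and over-expression
#'
#' For each couple, over the samples shared by the copy-number and
#' expression matrices: the fraction of amplified cells (either member at
#' code 2) that are also up-called (either member `up`), and the fraction of
#' up-called cells that are also amplified. Fractions with an empty
#' denominator are reported NA. The attribute `topk_overlap` gives the
#' overlap between the CNA top-k and the expression top-k couple lists.
#'
#' @param cohort a [cohort()] with both matrices.
#' @param zcalls `zscore_matrix` or call matrix.
#' @param aligned an `aligned_couples` object.
#' @param summary optional precomputed `coalteration_summary` (used for the
#'   top-k overlap); computed if missing.
#' @param k top-k size for the overlap statistic.
#' @return data frame, one row per couple, with counts and the two
#'   conditional fractions; attributes `topk_overlap` (count),
#'   `topk_cna`/`topk_expr` (label vectors).
#' @export
cna_expression_concordance <- function(cohort, zcalls, aligned,
                                       summary = NULL, k = 10L) {
  cc <- couple_calls(zcalls, aligned)
  cpl <- cc$couples
  samples <- intersect(colnames(cohort$cna), colnames(cc$sno))
  if (length(samples) == 0L) stop("no shared samples between CNA and Z-scores")
  codes <- unclass(cohort$cna)
  S <- codes[cpl$snorna_id, samples, drop = FALSE]
  H <- codes[cpl$host_id, samples, drop = FALSE]
  amp <- (!is.na(S) & S == 2L) | (!is.na(H) & H == 2L)
  up <- cc$sno[, samples, drop = FALSE] == "up" |
    cc$host[, samples, drop = FALSE] == "up"
  n_amp <- rowSums(amp)
  n_up <- rowSums(up)
  n_both <- rowSums(amp & up)
  out <- data.frame(
    key = couple_key(cpl), label = couple_label(cpl),
    n_samples = length(samples), n_amplified = n_amp, n_up = n_up,
    n_amplified_and_up = n_both,
    frac_amplified_up = ifelse(n_amp > 0L, n_both / n_amp, NA_real_),
    frac_up_amplified = ifelse(n_up > 0L, n_both / n_up, NA_real_),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (is.null(summary)) summary <- summarize_cohort(cohort, aligned)
  top_cna <- top_k_couples(summary, k)$label
  top_expr <- top_k_upregulated(zcalls, aligned, k)$label
  attr(out, "topk_cna") <- top_cna
  attr(out, "topk_expr") <- top_expr
  attr(out, "topk_overlap") <- length(intersect(top_cna, top_expr))
  out
}
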