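#' Two-sided Fisher exact test for a 2x2 table
#'
#' Implemented from first principles: conditioning on the table margins, the
#' count in the top-left cell follows a hypergeometric distribution whose
#' probabilities are evaluated with log-space factorials (stable up to
#' totals around 1e6). The two-sided p-value is the probability-method sum:
#' the total probability of all tables with the same margins whose
#' probability does not exceed that of the observed table, with a relative
#' tolerance of 1e-7 on the comparison. A table with any zero margin admits
#' only one configuration, and p = 1 by convention (logged).
#'
#' @param a,b,c,d non-negative integer counts of the table
#'   \code{rbind(c(a, b), c(c, d))}; alternatively `a` may be a 2x2 matrix
#'   and the others omitted.
#' @return the two-sided p-value in (0, 1].
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    d <- a[2L, 2L]; c <- a[2L, 1L]; b <- a[1L, 2L]; a <- a[1L, 1L]
  }
  cnt <- c(a, b, c, d)
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt))) {
    stop("counts must be non-negative integers")
  }
  n <- a + b + c + d
  if (n < 1L) stop("empty table")
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) {
    sno_log("fisher", "zero margin: p = 1 by convention", "debug")
    return(1)
  }
  k <- max(0, c1 - r2):min(c1, r1)
  logp <- lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1)
  logp_obs <- logp[match(a, k)]
  p <- sum(exp(logp[logp <= logp_obs + log1p(1e-7)]))
  min(p, 1)
}

#' Association between snoRNA and host alteration across samples
#'
#' For every aligned couple, builds the 2x2 table of "snoRNA altered
#' (deep CNA event) yes/no" against "host altered yes/no" over the cohort's
#' samples with both codes present, and tests independence with
#' [fisher_exact()]. The odds ratio is the sample cross-product ratio; when
#' any cell is zero the Haldane 0.5 continuity correction is applied and
#' flagged. Raw p-values are adjusted across all couples of the cohort with
#' Benjamini-Hochberg.
#'
#' @param cohort a [cohort()].
#' @param aligned an `aligned_couples` object.
#' @return data frame, one row per couple: counts `a` (both altered), `b`
#'   (snoRNA only), `c` (host only), `d` (neither), `odds_ratio`,
#'   `continuity_corrected`, `p_raw`, `p_bh`.
#' @export
couple_association <- function(cohort, aligned) {
  stopifnot(inherits(cohort, "cohort"), inherits(aligned, "aligned_couples"))
  cpl <- aligned$couples
  if (nrow(cpl) == 0L) stop("empty couple set after alignment")
  codes <- unclass(cohort$cna)
  S <- codes[cpl$snorna_id, , drop = FALSE]
  H <- codes[cpl$host_id, , drop = FALSE]
  ok <- !is.na(S) & !is.na(H)
  s_alt <- ok & abs(S) == 2L
  h_alt <- ok & abs(H) == 2L
  a <- rowSums(s_alt & h_alt)
  b <- rowSums(s_alt & !h_alt & ok)
  cc <- rowSums(!s_alt & h_alt & ok)
  d <- rowSums(ok) - a - b - cc
  p <- vapply(seq_len(nrow(cpl)), function(i) fisher_exact(a[i], b[i], cc[i], d[i]),
              numeric(1L))
  zero <- a == 0 | b == 0 | cc == 0 | d == 0
  or <- ifelse(zero,
               ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5)),
               (a * d) / (b * cc))
  out <- data.frame(
    cohort = cohort$acronym, key = couple_key(cpl), label = couple_label(cpl),
    a = a, b = b, c = cc, d = d,
    odds_ratio = or, continuity_corrected = zero,
    p_raw = p, p_bh = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
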