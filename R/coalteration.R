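EVENT_CLASSES <- c("none", "snorna_only", "host_only", "co_occurring")

check_codes <- function(code) {
  bad <- !is.na(code) & !(code %in% GISTIC_CODES)
  if (any(bad)) {
    stop(sprintf("invalid copy-number code(s): %s",
                 paste(unique(code[bad]), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Is a discrete copy-number code a CNA event?
#'
#' The analysis restricts "CNA event" to the deep calls: high-level
#' amplification (code 2) and homozygous deep deletion (code -2). Shallow
#' deletions (-1), low-level gains (1) and diploid cells (0) are not events.
#' Missing codes are flagged and never count as events.
#'
#' @param code integer vector of GISTIC codes in \{-2,...,2\} or NA.
#' @return data frame with logical `event`, character `sign`
#'   (`amp`/`del`/`none`) and logical `missing`, one row per input code.
#' @export
is_event <- function(code) {
  check_codes(code)
  miss <- is.na(code)
  ev <- !miss & abs(code) == 2L
  sign <- rep("none", length(code))
  sign[ev & code == 2L] <- "amp"
  sign[ev & code == -2L] <- "del"
  data.frame(event = ev, sign = sign, missing = miss)
}

#' Classify one (couple, sample) cell
#'
#' Combines the snoRNA and host copy-number codes of a sample into an event
#' class: `none` (neither member carries a deep event), `snorna_only`,
#' `host_only`, or `co_occurring` (both members altered). For co-occurring
#' cells `concordant` records whether the two events share a sign
#' (amp/amp or del/del); co-occurrence itself does not require sign
#' concordance. A cell with a missing code on either side is classed
#' `missing` and excluded from downstream counts.
#'
#' @param snorna_code,host_code equal-length integer vectors of GISTIC codes.
#' @return data frame with columns `class`, `sign_snorna`, `sign_host`,
#'   `concordant` (NA unless co-occurring).
#' @export
classify_cell <- function(snorna_code, host_code) {
  stopifnot(length(snorna_code) == length(host_code))
  s <- is_event(snorna_code)
  h <- is_event(host_code)
  miss <- s$missing | h$missing
  cls <- rep("none", length(snorna_code))
  cls[s$event & !h$event] <- "snorna_only"
  cls[!s$event & h$event] <- "host_only"
  cls[s$event & h$event] <- "co_occurring"
  cls[miss] <- "missing"
  sign_s <- ifelse(miss, "none", s$sign)
  sign_h <- ifelse(miss, "none", h$sign)
  conc <- ifelse(cls == "co_occurring", sign_s == sign_h, NA)
  data.frame(class = factor(cls, levels = c(EVENT_CLASSES, "missing")),
             sign_snorna = sign_s, sign_host = sign_h, concordant = conc)
}

#' Summarize CNA co-alteration of one cohort
#'
#' Classifies every (couple, sample) cell of the cohort and aggregates:
#' cell counts per event class, amplification/deletion breakdowns, per-sample
#' event rates, the cumulative alteration frequency (altered cells over
#' non-missing cells, i.e. couples x samples minus missing), per-couple
#' altered-sample fractions, and couple-level co-occurrence classes
#' (`co_occurring` if the couple has at least one co-occurring cell,
#' `altered_non_co` if altered but never jointly, `absent` otherwise).
#'
#' The amp/del breakdown counts the snoRNA-side sign for the `snorna_only`
#' and `co_occurring` contexts and the host-side sign for `host_only`;
#' host-side signs of co-occurring cells are kept in `host_co_signs` as a
#' companion.
#'
#' @param cohort a [cohort()].
#' @param aligned an `aligned_couples` object from [align_couples()].
#' @param event_counting `"cell"` (an altered cell counts once in the
#'   cumulative-frequency numerator, the default) or `"gene"` (a co-occurring
#'   cell contributes two gene-level events).
#' @return object of class `coalteration_summary`.
#' @export
summarize_cohort <- function(cohort, aligned,
                             event_counting = c("cell", "gene")) {
  event_counting <- match.arg(event_counting)
  stopifnot(inherits(cohort, "cohort"), inherits(aligned, "aligned_couples"))
  cpl <- aligned$couples
  if (nrow(cpl) == 0L) stop("empty couple set after alignment")
  n_samples <- ncol(cohort$cna)
  n_couples <- nrow(cpl)
  codes <- unclass(cohort$cna)
  S <- codes[cpl$snorna_id, , drop = FALSE]
  H <- codes[cpl$host_id, , drop = FALSE]
  check_codes(S); check_codes(H)

  miss <- is.na(S) | is.na(H)
  sev <- !miss & abs(S) == 2L
  hev <- !miss & abs(H) == 2L
  co <- sev & hev
  sno_only <- sev & !hev
  host_only <- hev & !sev
  altered <- sev | hev

  cell_counts <- c(none = sum(!miss & !altered), snorna_only = sum(sno_only),
                   host_only = sum(host_only), co_occurring = sum(co))
  n_missing <- sum(miss)
  stopifnot(sum(cell_counts) + n_missing == n_couples * n_samples)

  amp_del <- rbind(
    snorna_only = c(amp = sum(sno_only & S == 2L), del = sum(sno_only & S == -2L)),
    co_occurring = c(amp = sum(co & S == 2L), del = sum(co & S == -2L)),
    host_only = c(amp = sum(host_only & H == 2L), del = sum(host_only & H == -2L)))
  host_co_signs <- c(amp = sum(co & H == 2L), del = sum(co & H == -2L))
  concordant_co <- sum(co & sign(S) == sign(H))

  denom_cells <- n_couples * n_samples - n_missing
  n_altered_cells <- sum(altered)
  n_gene_events <- sum(sev) + sum(hev)
  numerator <- if (event_counting == "cell") n_altered_cells else n_gene_events
  cumulative_frequency <- if (denom_cells > 0L) numerator / denom_cells else NA_real_

  per_sample_rates <- cell_counts[c("snorna_only", "host_only", "co_occurring")] / n_samples

  nonmiss_by_couple <- as.integer(rowSums(!miss))
  altered_by_couple <- as.integer(rowSums(altered))
  co_by_couple <- as.integer(rowSums(co))
  couple_class <- ifelse(co_by_couple > 0L, "co_occurring",
                         ifelse(altered_by_couple > 0L, "altered_non_co", "absent"))
  couples_df <- data.frame(
    key = couple_key(cpl), label = couple_label(cpl),
    snorna_id = cpl$snorna_id, host_id = cpl$host_id,
    snorna_symbol = cpl$snorna_symbol, host_symbol = cpl$host_symbol,
    n_nonmissing = nonmiss_by_couple, n_altered = altered_by_couple,
    n_co_occurring = co_by_couple,
    altered_sample_fraction = ifelse(nonmiss_by_couple > 0L,
                                     altered_by_couple / nonmiss_by_couple, NA_real_),
    couple_class = couple_class,
    stringsAsFactors = FALSE)
  rownames(couples_df) <- NULL

  structure(list(
    acronym = cohort$acronym, n_samples = n_samples, n_couples = n_couples,
    cell_counts = cell_counts, n_missing_cells = n_missing,
    amp_del_counts = amp_del, host_co_signs = host_co_signs,
    n_concordant_co = concordant_co,
    n_discordant_co = sum(co) - concordant_co,
    per_sample_rates = per_sample_rates,
    n_altered_cells = n_altered_cells, n_gene_events = n_gene_events,
    cumulative_frequency = cumulative_frequency,
    event_counting = event_counting,
    couples = couples_df), class = "coalteration_summary")
}

#' @export
print.coalteration_summary <- function(x, ...) {
  cat(sprintf("<coalteration_summary %s> %d couples x %d samples\n",
              x$acronym, x$n_couples, x$n_samples))
  cat(sprintf("  cells: none=%d snorna_only=%d host_only=%d co_occurring=%d missing=%d\n",
              x$cell_counts["none"], x$cell_counts["snorna_only"],
              x$cell_counts["host_only"], x$cell_counts["co_occurring"],
              x$n_missing_cells))
  cat(sprintf("  cumulative CNA frequency (%s events): %.4f\n",
              x$event_counting, x$cumulative_frequency))
  invisible(x)
}

#' Cross-cohort recurrence categories of couples
#'
#' For every couple in the input set, collects the cohorts in which it is
#' measurable (both members in the copy-number matrix) and those in which it
#' carries at least one altered cell, then assigns a category: `never`
#' (altered in no cohort), `all` (altered in every cohort analyzed) or `some`
#' (anything in between). Couples measurable in no cohort are reported
#' separately as `not_evaluable` and excluded from the percentages, which
#' are over evaluable couples and sum to 100.
#'
#' @param summaries named list of `coalteration_summary`, one per cohort.
#' @param couples the full `couple_set` the summaries were derived from.
#' @return data frame with per-couple `category`, `n_cohorts_present`,
#'   `n_cohorts_altered` and `altered_in` (comma-separated acronyms), with
#'   attribute `percentages` (named `never`/`all`/`some`, summing to 100) and
#'   attribute `n_not_evaluable`.
#' @export
cross_cohort_categories <- function(summaries, couples) {
  stopifnot(length(summaries) >= 1L)
  acronyms <- vapply(summaries, `[[`, character(1L), "acronym")
  n_cohorts <- length(summaries)
  keys <- couple_key(couples)
  present <- matrix(FALSE, nrow = length(keys), ncol = n_cohorts,
                    dimnames = list(keys, acronyms))
  altered <- present
  for (j in seq_along(summaries)) {
    s <- summaries[[j]]$couples
    present[match(s$key, keys), j] <- TRUE
    altered[match(s$key[s$n_altered > 0L], keys), j] <- TRUE
  }
  n_present <- rowSums(present)
  n_altered <- rowSums(altered)
  category <- ifelse(n_present == 0L, "not_evaluable",
                     ifelse(n_altered == 0L, "never",
                            ifelse(n_altered == n_cohorts, "all", "some")))
  out <- data.frame(
    key = keys, label = couple_label(couples),
    snorna_id = couples$snorna_id, host_id = couples$host_id,
    n_cohorts_present = n_present, n_cohorts_altered = n_altered,
    altered_in = vapply(seq_along(keys), function(i)
      paste(acronyms[altered[i, ]], collapse = ","), character(1L)),
    category = category, stringsAsFactors = FALSE)
  evaluable <- out$category != "not_evaluable"
  pct <- 100 * vapply(c("never", "all", "some"),
                      function(cat) sum(out$category[evaluable] == cat),
                      numeric(1L)) / max(sum(evaluable), 1L)
  attr(out, "percentages") <- pct
  attr(out, "n_not_evaluable") <- sum(!evaluable)
  out
}

#' Top-k most frequently altered couples of a cohort
#'
#' Ranks couples by the fraction of (non-missing) samples in which the couple
#' carries at least one deep CNA event. Ties are broken deterministically:
#' descending fraction, then ascending `snorna_symbol/host_symbol` label,
#' then ascending snoRNA id.
#'
#' @param summary a `coalteration_summary`.
#' @param k number of couples to return (default 10); fewer are returned if
#'   the cohort has fewer couples.
#' @return data frame with `rank`, couple identifiers and
#'   `altered_sample_fraction`.
#' @export
top_k_couples <- function(summary, k = 10L) {
  stopifnot(inherits(summary, "coalteration_summary"), k >= 1L)
  df <- summary$couples
  ord <- order(-df$altered_sample_fraction, df$label, df$snorna_id,
               method = "radix")
  df <- df[ord, , drop = FALSE]
  df <- utils::head(df, min(as.integer(k), nrow(df)))
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df[, c("rank", "key", "label", "snorna_id", "host_id",
         "n_altered", "n_nonmissing", "altered_sample_fraction")]
}
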