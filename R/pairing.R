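#' Build a validated snoRNA/host couple table
#'
#' Each couple pairs one intronic snoRNA with the gene that hosts it in an
#' intron. Rows are kept only if both Ensembl-style identifiers are present
#' and the host biotype is `protein_coding` or `lncRNA`; every exclusion is
#' logged with a reason. A snoRNA hosted by several genes (or a host with
#' several snoRNAs) yields several independent couples; exact duplicates on
#' `(snorna_id, host_id)` are collapsed to the first occurrence.
#'
#' @param records data frame with columns `snorna_id`, `snorna_symbol`,
#'   `host_id`, `host_symbol`, `box_class` (`CD`, `HACA` or other) and
#'   `host_biotype` (`protein_coding` or `lncRNA`). Symbol/annotation columns
#'   may be missing and are filled with defaults.
#' @return data frame of class `couple_set` with one row per retained couple
#'   and an attribute `dropped` (data frame of excluded rows with a `reason`
#'   column).
#' @export
build_couples <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("snorna_id", "host_id")
  if (!all(need %in% colnames(records))) {
    stop("pairing records need columns snorna_id and host_id")
  }
  df <- records
  for (col in c("snorna_symbol", "host_symbol")) {
    if (is.null(df[[col]])) df[[col]] <- NA_character_
  }
  if (is.null(df$box_class)) df$box_class <- "other"
  if (is.null(df$host_biotype)) df$host_biotype <- NA_character_
  df <- df[, c("snorna_id", "snorna_symbol", "host_id", "host_symbol",
               "box_class", "host_biotype")]
  for (j in seq_along(df)) df[[j]] <- as.character(df[[j]])

  blank <- function(x) is.na(x) | !nzchar(trimws(x))
  reason <- rep(NA_character_, nrow(df))
  reason[blank(df$snorna_id) | blank(df$host_id)] <- "missing ensembl id"
  ok_bio <- df$host_biotype %in% c("protein_coding", "lncRNA")
  reason[is.na(reason) & !ok_bio] <- "host biotype not protein_coding/lncRNA"
  same <- is.na(reason) & df$snorna_id == df$host_id
  reason[same] <- "snorna_id equals host_id"
  key <- paste(df$snorna_id, df$host_id, sep = "\r")
  dup <- is.na(reason) & duplicated(replace(key, !is.na(reason), NA))
  reason[dup] <- "duplicate couple"

  dropped <- df[!is.na(reason), , drop = FALSE]
  if (nrow(dropped) > 0L) {
    dropped$reason <- reason[!is.na(reason)]
    sno_log("pairing", sprintf("excluded %d pairing row(s): %s", nrow(dropped),
                               paste(sprintf("%s/%s (%s)", dropped$snorna_id,
                                             dropped$host_id, dropped$reason),
                                     collapse = "; ")), "warn")
  } else {
    dropped$reason <- character(0L)
  }
  kept <- df[is.na(reason), , drop = FALSE]
  if (nrow(kept) == 0L) stop("no valid couples")
  blank_sym <- blank(kept$snorna_symbol)
  kept$snorna_symbol[blank_sym] <- kept$snorna_id[blank_sym]
  blank_sym <- blank(kept$host_symbol)
  kept$host_symbol[blank_sym] <- kept$host_id[blank_sym]
  kept$box_class[!(kept$box_class %in% c("CD", "HACA"))] <- "other"
  rownames(kept) <- NULL
  rownames(dropped) <- NULL
  structure(kept, dropped = dropped, class = c("couple_set", "data.frame"))
}

#' Read a snoRNA/host pairing table from TSV
#'
#' Reads the minimal join-ready dialect (`snorna_id`, `snorna_symbol`,
#' `host_id`, `host_symbol`, `box_class`, `host_biotype`, tab-separated) and
#' validates it with [build_couples()].
#'
#' @param path path to a tab-separated pairing table.
#' @return a `couple_set`, see [build_couples()].
#' @export
read_pairing_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA"), quote = "")
  build_couples(raw)
}

#' Write a pairing table as TSV
#' @param couples a `couple_set` or compatible data frame.
#' @param path output path.
#' @export
write_pairing_table <- function(couples, path) {
  write_table(as.data.frame(couples)[, c("snorna_id", "snorna_symbol",
                                         "host_id", "host_symbol",
                                         "box_class", "host_biotype")], path)
}

#' Align a couple set to a cohort's matrices
#'
#' Couples whose snoRNA or host gene is absent from the cohort's copy-number
#' matrix are set aside with a reason; the retained couples keep the input
#' ordering. Retained plus dropped always partition the input.
#'
#' @param couples a `couple_set` from [build_couples()].
#' @param cohort a [cohort()].
#' @return list of class `aligned_couples` with elements `couples` (retained
#'   rows), `dropped` (data frame with a `reason` column) and `acronym`.
#' @export
align_couples <- function(couples, cohort) {
  stopifnot(inherits(cohort, "cohort"))
  genes <- rownames(cohort$cna)
  sno_in <- couples$snorna_id %in% genes
  host_in <- couples$host_id %in% genes
  reason <- rep(NA_character_, nrow(couples))
  reason[!host_in] <- "host_id not in CNA matrix"
  reason[!sno_in] <- "snorna_id not in CNA matrix"
  reason[!sno_in & !host_in] <- "both ids not in CNA matrix"
  keep <- is.na(reason)
  dropped <- as.data.frame(couples)[!keep, , drop = FALSE]
  dropped$reason <- reason[!keep]
  if (nrow(dropped) > 0L) {
    sno_log("pairing", sprintf("cohort %s: %d couple(s) not measurable",
                               cohort$acronym, nrow(dropped)), "warn")
  }
  retained <- as.data.frame(couples)[keep, , drop = FALSE]
  rownames(retained) <- NULL
  rownames(dropped) <- NULL
  structure(list(couples = retained, dropped = dropped,
                 acronym = cohort$acronym),
            class = "aligned_couples")
}

# Canonical display label of a couple, used for reporting and tie-breaking.
couple_label <- function(couples) {
  paste(couples$snorna_symbol, couples$host_symbol, sep = "/")
}

# Canonical join key of a couple.
couple_key <- function(couples) {
  paste(couples$snorna_id, couples$host_id, sep = "|")
}
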