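#' Parameters of the synthetic multi-cohort generator
#'
#' The generator emulates the joint structure the pipeline measures: loci
#' where a tumor sample may carry a deep copy-number event hitting the
#' snoRNA, its host gene, or both, with amplification/deletion mixing, sign
#' concordance, nuisance shallow codes, optional missing cells, and
#' log-normal expression with a multiplicative gene-dosage effect.
#'
#' Per (couple, sample) cell: with probability `p_alt` the locus is altered;
#' given an alteration, both members are hit with probability `p_co`,
#' otherwise a single member (the snoRNA with probability
#' `p_sno_given_single`). Each event is an amplification with probability
#' `p_amp`, else a deep deletion; a joint event shares one sign with
#' probability `p_sign_concord`, otherwise the two members get opposite
#' signs. Cells left diploid receive a spurious shallow code (+/-1) with
#' probability `p_shallow`. Expression of gene g in a sample is
#' `exp(mu_g + N(0, noise_sd)) * m(code)` with per-gene baseline
#' `mu_g ~ N(expr_log_location, expr_log_scale)` and dosage multiplier
#' `m = f_amp` for code 2, `f_del` for code -2, and 1 otherwise.
#'
#' @param n_couples number of snoRNA/host couples (default 295).
#' @param n_samples samples per cohort.
#' @param acronyms character vector of cohort labels.
#' @param p_alt per-couple probability that a given sample carries an
#'   alteration at the locus; a scalar (shared by all couples) or a vector
#'   with one value per couple, which lets a fraction of couples be
#'   effectively unalterable (rate 0) as real couple sets are.
#' @param p_co probability an alteration hits both members.
#' @param p_sno_given_single probability a single-member hit is the snoRNA.
#' @param p_amp probability an event is an amplification.
#' @param p_sign_concord probability a joint event is sign-concordant.
#' @param p_shallow spurious shallow-code rate on diploid cells.
#' @param p_missing per-gene-cell missing-code rate (default 0).
#' @param expr_log_location,expr_log_scale log-scale baseline distribution.
#' @param f_amp,f_del dosage multipliers (f_del < 1 < f_amp).
#' @param noise_sd log-scale multiplicative noise sd.
#' @param rng_seed integer seed; identical seeds give bit-identical output.
#' @return validated list of class `generator_params`.
#' @export
generator_params <- function(n_couples = 295L, n_samples = 100L,
                             acronyms = "SYN1",
                             p_alt = 0.05, p_co = 0.5,
                             p_sno_given_single = 0.5, p_amp = 0.7,
                             p_sign_concord = 0.9, p_shallow = 0.1,
                             p_missing = 0,
                             expr_log_location = log(1000),
                             expr_log_scale = 1,
                             f_amp = 4, f_del = 0.25, noise_sd = 0.5,
                             rng_seed = 1L) {
  p <- list(n_couples = as.integer(n_couples), n_samples = as.integer(n_samples),
            acronyms = as.character(acronyms), p_alt = p_alt, p_co = p_co,
            p_sno_given_single = p_sno_given_single, p_amp = p_amp,
            p_sign_concord = p_sign_concord, p_shallow = p_shallow,
            p_missing = p_missing, expr_log_location = expr_log_location,
            expr_log_scale = expr_log_scale, f_amp = f_amp, f_del = f_del,
            noise_sd = noise_sd, rng_seed = as.integer(rng_seed))
  probs <- p[c("p_alt", "p_co", "p_sno_given_single", "p_amp",
               "p_sign_concord", "p_shallow", "p_missing")]
  if (any(unlist(probs) < 0 | unlist(probs) > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (!length(p$p_alt) %in% c(1L, p$n_couples)) {
    stop("p_alt must be a scalar or one value per couple")
  }
  if (p$n_couples < 1L || p$n_samples < 1L) stop("n_couples and n_samples must be >= 1")
  if (length(p$acronyms) < 1L || anyDuplicated(p$acronyms) || any(!nzchar(p$acronyms))) {
    stop("acronyms must be non-empty and unique")
  }
  # f_amp = 1 (and f_del = 1) is allowed: it switches the dosage effect off,
  # which the null-coupling checks rely on.
  if (!(p$f_del <= 1 && 1 <= p$f_amp)) stop("need f_del <= 1 <= f_amp")
  if (p$noise_sd < 0 || p$expr_log_scale < 0) stop("scales must be non-negative")
  structure(p, class = "generator_params")
}

#' Generate a synthetic pairing table plus cohorts with known truth
#'
#' Draws the pairing table, one copy-number and one expression matrix per
#' cohort under [generator_params()], and returns alongside them a truth
#' record: the parameters, per-gene expression baselines, and realized
#' per-couple, per-cohort counts of every event class (including masked
#' cells). The truth counts are re-derived from the emitted matrices before
#' returning, so they are consistent with what a consumer of the files will
#' see. Identical seeds give bit-identical output.
#'
#' @param params a `generator_params` object.
#' @return list with `couples` (a `couple_set`), `cohorts` (named list of
#'   [cohort()]) and `truth` (list with `params`, `baselines`,
#'   `class_counts` data frame, `sign_counts` data frame).
#' @export
generate_cohorts <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$rng_seed)
  nc <- params$n_couples
  ns <- params$n_samples

  sno_ids <- sprintf("ENSGSYNS%05d", seq_len(nc))
  host_ids <- sprintf("ENSGSYNH%05d", seq_len(nc))
  pairing <- data.frame(
    snorna_id = sno_ids,
    snorna_symbol = sprintf("SNOSYN%03d", seq_len(nc)),
    host_id = host_ids,
    host_symbol = sprintf("HGSYN%03d", seq_len(nc)),
    box_class = sample(c("CD", "HACA"), nc, replace = TRUE, prob = c(0.6, 0.4)),
    host_biotype = sample(c("protein_coding", "lncRNA"), nc, replace = TRUE,
                          prob = c(0.8, 0.2)),
    stringsAsFactors = FALSE)
  couples <- build_couples(pairing)

  gene_ids <- as.vector(rbind(sno_ids, host_ids))
  gene_symbols <- as.vector(rbind(pairing$snorna_symbol, pairing$host_symbol))
  mu <- stats::rnorm(2L * nc, params$expr_log_location, params$expr_log_scale)
  names(mu) <- gene_ids

  draw_sign <- function(n) ifelse(stats::runif(n) < params$p_amp, 2L, -2L)

  cohorts <- list()
  class_counts <- list()
  sign_counts <- list()
  for (acr in params$acronyms) {
    S <- matrix(0L, nc, ns)
    H <- matrix(0L, nc, ns)
    altered <- matrix(stats::runif(nc * ns) < params$p_alt, nc, ns)
    co <- altered & matrix(stats::runif(nc * ns) < params$p_co, nc, ns)
    single <- altered & !co
    sno_single <- single & matrix(stats::runif(nc * ns) < params$p_sno_given_single, nc, ns)
    host_single <- single & !sno_single

    S[sno_single] <- draw_sign(sum(sno_single))
    H[host_single] <- draw_sign(sum(host_single))
    n_co <- sum(co)
    if (n_co > 0L) {
      concord <- stats::runif(n_co) < params$p_sign_concord
      s_sign <- draw_sign(n_co)
      h_sign <- ifelse(concord, s_sign, -s_sign)
      S[co] <- s_sign
      H[co] <- h_sign
    }
    shallow_s <- S == 0L & matrix(stats::runif(nc * ns) < params$p_shallow, nc, ns)
    S[shallow_s] <- ifelse(stats::runif(sum(shallow_s)) < 0.5, 1L, -1L)
    shallow_h <- H == 0L & matrix(stats::runif(nc * ns) < params$p_shallow, nc, ns)
    H[shallow_h] <- ifelse(stats::runif(sum(shallow_h)) < 0.5, 1L, -1L)
    if (params$p_missing > 0) {
      S[matrix(stats::runif(nc * ns) < params$p_missing, nc, ns)] <- NA_integer_
      H[matrix(stats::runif(nc * ns) < params$p_missing, nc, ns)] <- NA_integer_
    }

    codes <- matrix(0L, 2L * nc, ns, dimnames = list(
      gene_ids, sprintf("%s-S%04d", acr, seq_len(ns))))
    codes[seq(1L, 2L * nc, by = 2L), ] <- S
    codes[seq(2L, 2L * nc, by = 2L), ] <- H
    cna <- cna_matrix(codes, gene_symbols = gene_symbols)

    mult <- matrix(1, 2L * nc, ns)
    mult[!is.na(codes) & codes == 2L] <- params$f_amp
    mult[!is.na(codes) & codes == -2L] <- params$f_del
    vals <- exp(mu + matrix(stats::rnorm(2L * nc * ns, 0, params$noise_sd),
                            2L * nc, ns)) * mult
    dimnames(vals) <- dimnames(codes)
    expr <- expr_matrix(vals, gene_symbols = gene_symbols)
    cohorts[[acr]] <- cohort(acr, cna, expr)

    # truth recounted from the emitted codes (so masking/shallow are reflected)
    miss <- is.na(S) | is.na(H)
    sev <- !miss & abs(S) == 2L
    hev <- !miss & abs(H) == 2L
    class_counts[[acr]] <- data.frame(
      cohort = acr, key = couple_key(pairing),
      n_none = rowSums(!miss & !sev & !hev),
      n_snorna_only = rowSums(sev & !hev),
      n_host_only = rowSums(hev & !sev),
      n_co_occurring = rowSums(sev & hev),
      n_missing = rowSums(miss),
      stringsAsFactors = FALSE)
    sign_counts[[acr]] <- data.frame(
      cohort = acr,
      n_amp = sum(S == 2L, na.rm = TRUE) + sum(H == 2L, na.rm = TRUE),
      n_del = sum(S == -2L, na.rm = TRUE) + sum(H == -2L, na.rm = TRUE),
      n_co_concordant = sum(sev & hev & sign(S) == sign(H), na.rm = TRUE),
      stringsAsFactors = FALSE)
  }
  class_counts <- do.call(rbind, c(class_counts, make.row.names = FALSE))
  stopifnot(all(rowSums(class_counts[, c("n_none", "n_snorna_only", "n_host_only",
                                         "n_co_occurring", "n_missing")]) == ns))
  truth <- list(params = params,
                baselines = data.frame(gene_id = gene_ids, log_mu = unname(mu),
                                       stringsAsFactors = FALSE),
                class_counts = class_counts,
                sign_counts = do.call(rbind, c(sign_counts, make.row.names = FALSE)))
  list(couples = couples, cohorts = cohorts, truth = truth)
}

#' Named generator presets
#'
#' Three documented regimes bracketing the cohort behaviors the pipeline is
#' meant to resolve: `kirc_like` (low alteration burden, strong
#' co-occurrence, p_co = 0.75 so co-occurring cells outnumber single-member
#' cells 3:1 in expectation), `ov_like` (high burden, balanced
#' co-occurrence) and `brca_like` (moderate burden, mostly decoupled events,
#' p_co = 0.3).
#'
#' @param name preset name; `NULL` returns the list of all presets.
#' @param ... overrides forwarded to [generator_params()] (e.g. `n_samples`,
#'   `rng_seed`).
#' @return a `generator_params` object, or a named list of them.
#' @export
scenario_presets <- function(name = NULL, ...) {
  build <- function(acr, ...) generator_params(acronyms = acr, ...)
  presets <- list(
    kirc_like = function(...) build("KIRCSYN", p_alt = 0.02, p_co = 0.75,
                                    p_amp = 0.6, ...),
    ov_like = function(...) build("OVSYN", p_alt = 0.15, p_co = 0.5,
                                  p_amp = 0.7, ...),
    brca_like = function(...) build("BRCASYN", p_alt = 0.08, p_co = 0.3,
                                    p_amp = 0.7, ...))
  if (is.null(name)) return(lapply(presets, function(f) f(...)))
  if (!name %in% names(presets)) {
    stop(sprintf("unknown preset '%s'; valid presets: %s", name,
                 paste(names(presets), collapse = ", ")))
  }
  presets[[name]](...)
}
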