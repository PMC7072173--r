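# Independent reference implementations kept deliberately naive: nested
# loops and exhaustive enumeration, never sharing code with the package.

random_cna <- function(n_genes, n_samples, p_missing = 0,
                       codes = -2:2, prob = c(.05, .1, .6, .15, .1)) {
  m <- matrix(sample(codes, n_genes * n_samples, replace = TRUE, prob = prob),
              n_genes, n_samples)
  if (p_missing > 0) m[runif(length(m)) < p_missing] <- NA
  cna_matrix(m, gene_ids = sprintf("G%03d", seq_len(n_genes)),
             sample_ids = sprintf("S%03d", seq_len(n_samples)))
}

random_expr <- function(n_genes, n_samples) {
  m <- matrix(rlnorm(n_genes * n_samples, 5, 1), n_genes, n_samples)
  expr_matrix(m, gene_ids = sprintf("G%03d", seq_len(n_genes)),
              sample_ids = sprintf("S%03d", seq_len(n_samples)))
}

# Random cohort of n_couples couples (genes interleaved sno/host).
random_cohort <- function(n_couples, n_samples, acronym = "T1",
                          p_missing = 0, with_expr = FALSE) {
  cna <- random_cna(2 * n_couples, n_samples, p_missing)
  expr <- if (with_expr) {
    expr_matrix(matrix(rlnorm(2 * n_couples * n_samples, 5, 1),
                       2 * n_couples, n_samples),
                gene_ids = rownames(cna), sample_ids = colnames(cna))
  } else NULL
  couples <- build_couples(data.frame(
    snorna_id = rownames(cna)[seq(1, 2 * n_couples, 2)],
    snorna_symbol = sprintf("SNO%03d", seq_len(n_couples)),
    host_id = rownames(cna)[seq(2, 2 * n_couples, 2)],
    host_symbol = sprintf("HG%03d", seq_len(n_couples)),
    box_class = "CD", host_biotype = "protein_coding"))
  list(cohort = cohort(acronym, cna, expr), couples = couples)
}

# Nested-loop classification of one cell.
oracle_classify <- function(s, h) {
  if (is.na(s) || is.na(h)) return("missing")
  se <- s %in% c(-2, 2); he <- h %in% c(-2, 2)
  if (se && he) "co_occurring" else if (se) "snorna_only" else if (he) "host_only" else "none"
}

# Nested-loop cohort counting over every (couple, sample) cell.
oracle_summary <- function(cna, couples) {
  counts <- c(none = 0, snorna_only = 0, host_only = 0, co_occurring = 0)
  n_missing <- 0
  per_couple_alt <- integer(nrow(couples))
  per_couple_nonmiss <- integer(nrow(couples))
  per_couple_co <- integer(nrow(couples))
  for (i in seq_len(nrow(couples))) {
    for (j in seq_len(ncol(cna))) {
      s <- cna[couples$snorna_id[i], j]
      h <- cna[couples$host_id[i], j]
      cl <- oracle_classify(s, h)
      if (cl == "missing") {
        n_missing <- n_missing + 1
      } else {
        counts[cl] <- counts[cl] + 1
        per_couple_nonmiss[i] <- per_couple_nonmiss[i] + 1
        if (cl != "none") per_couple_alt[i] <- per_couple_alt[i] + 1
        if (cl == "co_occurring") per_couple_co[i] <- per_couple_co[i] + 1
      }
    }
  }
  list(counts = counts, n_missing = n_missing,
       per_couple_alt = per_couple_alt,
       per_couple_nonmiss = per_couple_nonmiss,
       per_couple_co = per_couple_co)
}

# Exact two-sided Fisher p by integer enumeration (valid for small n:
# probabilities share the denominator choose(n, c1), so comparing exact
# integer numerators avoids any floating-point tie issues).
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  ks <- max(0, c1 - r2):min(c1, r1)
  num <- choose(r1, ks) * choose(r2, c1 - ks)
  num_obs <- num[ks == a]
  sum(num[num <= num_obs]) / choose(n, c1)
}

# Full-sort reference for top-k ranking.
oracle_topk <- function(df, k, frac_col) {
  ord <- order(-df[[frac_col]], df$label, df$snorna_id, method = "radix")
  head(df[ord, , drop = FALSE], min(k, nrow(df)))
}
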