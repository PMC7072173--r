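test_that("only deep calls are events; shallow and diploid codes are not", {
  ev <- is_event(c(2L, -2L, -1L, 0L, 1L, NA))
  expect_identical(ev$event, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(ev$sign, c("amp", "del", "none", "none", "none", "none"))
  expect_identical(ev$missing, c(rep(FALSE, 5), TRUE))
  expect_error(is_event(3L), "invalid")
})

test_that("cell classification matches a hand lookup on the full 5x5 grid", {
  grid <- expand.grid(s = -2:2, h = -2:2)
  got <- classify_cell(grid$s, grid$h)
  want <- mapply(oracle_classify, grid$s, grid$h)
  expect_identical(as.character(got$class), unname(want))
  # concordance defined only for co-occurring cells, true iff signs match
  co <- got$class == "co_occurring"
  expect_true(all(is.na(got$concordant[!co])))
  expect_identical(got$concordant[co],
                   sign(grid$s[co]) == sign(grid$h[co]))
  # missing on either side dominates
  expect_identical(as.character(classify_cell(NA_integer_, 2L)$class), "missing")
})

toy_cohort <- function() {
  codes <- rbind(A_sno = c(2L, 0L, 0L), A_host = c(2L, 0L, -2L),
                 B_sno = c(0L, 0L, 0L), B_host = c(0L, 1L, 0L))
  cna <- cna_matrix(codes, gene_ids = rownames(codes),
                    sample_ids = c("S1", "S2", "S3"))
  couples <- build_couples(data.frame(
    snorna_id = c("A_sno", "B_sno"), snorna_symbol = c("SNOA", "SNOB"),
    host_id = c("A_host", "B_host"), host_symbol = c("HGA", "HGB"),
    box_class = "CD", host_biotype = "protein_coding"))
  coh <- cohort("TOY", cna)
  list(cohort = coh, aligned = align_couples(couples, coh))
}

test_that("cohort summary reproduces hand counts on a toy cohort", {
  tc <- toy_cohort()
  s <- summarize_cohort(tc$cohort, tc$aligned)
  expect_identical(unname(s$cell_counts),
                   c(4L, 0L, 1L, 1L))  # none, snorna_only, host_only, co_occurring
  expect_equal(s$cumulative_frequency, 2 / 6)
  expect_identical(unname(s$amp_del_counts["co_occurring", "amp"]), 1L)
  expect_identical(unname(s$amp_del_counts["host_only", "del"]), 1L)
  expect_identical(s$n_concordant_co, 1L)
  # gene-level counting mode counts the co-occurring cell twice
  sg <- summarize_cohort(tc$cohort, tc$aligned, event_counting = "gene")
  expect_equal(sg$cumulative_frequency, 3 / 6)
})

test_that("an all-diploid cohort has zero frequency and all cells in 'none'", {
  cna <- cna_matrix(matrix(0L, 4, 5), gene_ids = sprintf("G%d", 1:4),
                    sample_ids = sprintf("S%d", 1:5))
  couples <- build_couples(data.frame(snorna_id = c("G1", "G3"),
                                      host_id = c("G2", "G4"),
                                      host_biotype = "protein_coding"))
  s <- summarize_cohort(cohort("D", cna), align_couples(couples, cohort("D", cna)))
  expect_equal(s$cumulative_frequency, 0)
  expect_identical(unname(s$cell_counts["none"]), 10L)
})

test_that("cohort counting matches the nested-loop oracle on random cohorts", {
  set.seed(21)
  for (rep in 1:25) {
    rc <- random_cohort(sample(3:10, 1), sample(4:12, 1), p_missing = 0.05)
    al <- align_couples(rc$couples, rc$cohort)
    s <- summarize_cohort(rc$cohort, al)
    o <- oracle_summary(unclass(rc$cohort$cna), al$couples)
    expect_equal(as.numeric(s$cell_counts), unname(o$counts))
    expect_equal(s$n_missing_cells, as.integer(o$n_missing))
    expect_equal(s$couples$n_altered, as.integer(o$per_couple_alt))
    expect_equal(s$couples$n_co_occurring, as.integer(o$per_couple_co))
    denom <- sum(o$counts)
    expect_equal(s$cumulative_frequency,
                 sum(o$counts[c("snorna_only", "host_only", "co_occurring")]) / denom)
    # conservation
    expect_identical(sum(s$cell_counts) + s$n_missing_cells,
                     s$n_couples * s$n_samples)
  }
})

test_that("cumulative frequency is permutation-invariant and monotone", {
  set.seed(22)
  rc <- random_cohort(8, 10)
  al <- align_couples(rc$couples, rc$cohort)
  s0 <- summarize_cohort(rc$cohort, al)
  perm <- unclass(rc$cohort$cna)[, sample(ncol(rc$cohort$cna))]
  perm <- perm[sample(nrow(perm)), ]
  sp <- summarize_cohort(cohort("P", cna_matrix(perm)),
                         align_couples(rc$couples, cohort("P", cna_matrix(perm))))
  expect_equal(sp$cumulative_frequency, s0$cumulative_frequency)
  # flipping one unaltered, fully diploid cell to an event cannot decrease it
  codes <- unclass(rc$cohort$cna)
  idx <- which(codes == 0L)[1]
  codes[idx] <- 2L
  s1 <- summarize_cohort(cohort("M", cna_matrix(codes)),
                         align_couples(rc$couples, cohort("M", cna_matrix(codes))))
  expect_gte(s1$cumulative_frequency, s0$cumulative_frequency)
})

test_that("cross-cohort categories match brute-force set logic", {
  set.seed(23)
  n_couples <- 10
  for (rep in 1:15) {
    n_cohorts <- sample(2:5, 1)
    cohorts <- list()
    couples <- NULL
    for (k in seq_len(n_cohorts)) {
      rc <- random_cohort(n_couples, 6, acronym = sprintf("C%d", k))
      cohorts[[sprintf("C%d", k)]] <- rc$cohort
      couples <- rc$couples  # identical gene universe by construction
    }
    summaries <- lapply(cohorts, function(coh)
      summarize_cohort(coh, align_couples(couples, coh)))
    cc <- cross_cohort_categories(summaries, couples)
    # brute force over couples x cohorts
    for (i in seq_len(n_couples)) {
      altered <- vapply(summaries, function(s) s$couples$n_altered[i] > 0, logical(1))
      want <- if (!any(altered)) "never" else if (all(altered)) "all" else "some"
      expect_identical(cc$category[i], want)
    }
    pct <- attr(cc, "percentages")
    expect_equal(sum(pct), 100)
  }
})

test_that("couples absent everywhere are reported not_evaluable, not 'never'", {
  rc <- random_cohort(3, 4)
  extra <- build_couples(rbind(as.data.frame(rc$couples),
                               data.frame(snorna_id = "GX1", snorna_symbol = "SNOX",
                                          host_id = "GX2", host_symbol = "HGX",
                                          box_class = "CD",
                                          host_biotype = "protein_coding")))
  s <- summarize_cohort(rc$cohort,
                        suppressMessages(align_couples(extra, rc$cohort)))
  cc <- cross_cohort_categories(list(T1 = s), extra)
  expect_identical(cc$category[cc$snorna_id == "GX1"], "not_evaluable")
  expect_identical(attr(cc, "n_not_evaluable"), 1L)
})

test_that("top-k ranking equals the full-sort oracle with deterministic ties", {
  set.seed(24)
  for (rep in 1:10) {
    rc <- random_cohort(12, 8)
    al <- align_couples(rc$couples, rc$cohort)
    s <- summarize_cohort(rc$cohort, al)
    for (k in c(1, 5, 20)) {
      top <- top_k_couples(s, k)
      want <- oracle_topk(s$couples, k, "altered_sample_fraction")
      expect_identical(top$key, want$key)
      expect_equal(top$altered_sample_fraction, want$altered_sample_fraction)
    }
  }
  # explicit tie: equal fractions ordered by ascending label
  codes <- rbind(a1 = c(2L, 0L), a2 = c(2L, 0L), b1 = c(0L, 2L), b2 = c(0L, 2L))
  cna <- cna_matrix(codes, gene_ids = rownames(codes), sample_ids = c("S1", "S2"))
  cpl <- build_couples(data.frame(
    snorna_id = c("b1", "a1"), snorna_symbol = c("SNOB", "SNOA"),
    host_id = c("b2", "a2"), host_symbol = c("HGB", "HGA"),
    host_biotype = "protein_coding"))
  s <- summarize_cohort(cohort("T", cna), align_couples(cpl, cohort("T", cna)))
  expect_identical(top_k_couples(s, 2)$label, c("SNOA/HGA", "SNOB/HGB"))
})
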