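expr_cna_pair <- function(vals, codes) {
  genes <- sprintf("G%02d", seq_len(nrow(vals)))
  samples <- sprintf("S%02d", seq_len(ncol(vals)))
  list(expr = expr_matrix(vals, genes, samples),
       cna = cna_matrix(codes, genes, samples))
}

test_that("Z-scores use the diploid reference with the n-1 denominator", {
  # reference {1,2,3} has mean 2, sd 1; the non-diploid sample at 4 gets z = 2,
  # which is 'normal' under the strict > 2 rule
  p <- expr_cna_pair(matrix(c(1, 2, 3, 4), 1), matrix(c(0L, 0L, 0L, 2L), 1))
  z <- compute_z(p$expr, p$cna)
  expect_equal(unname(z$z[1, ]), c(-1, 0, 1, 2))
  expect_identical(unname(z$reference_n[1]), 3)
  expect_identical(unname(classify_expression(z)[1, 4]), "normal")
})

test_that("degenerate references yield undefined cells", {
  # zero spread
  p <- expr_cna_pair(matrix(c(5, 5, 5, 9), 1), matrix(c(0L, 0L, 0L, 2L), 1))
  z <- suppressMessages(compute_z(p$expr, p$cna))
  expect_true(z$undefined_genes[1])
  expect_true(all(is.na(z$z[1, ])))
  # reference smaller than min_ref
  p <- expr_cna_pair(matrix(c(1, 2, 3, 4), 1), matrix(c(0L, 0L, 2L, 2L), 1))
  z <- suppressMessages(compute_z(p$expr, p$cna, min_ref = 3))
  expect_true(z$undefined_genes[1])
  expect_false(suppressMessages(compute_z(p$expr, p$cna, min_ref = 2))$undefined_genes[1])
  # no overlapping samples is a hard error
  e <- expr_matrix(matrix(1, 1, 1), "G1", "A")
  c2 <- cna_matrix(matrix(0L, 1, 1), "G1", "B")
  expect_error(compute_z(e, c2), "no overlapping samples")
})

test_that("Z computation matches a naive per-gene loop to 1e-9", {
  set.seed(31)
  for (rep in 1:10) {
    ng <- sample(3:8, 1); ns <- sample(6:15, 1)
    vals <- matrix(rlnorm(ng * ns, 4, 1), ng, ns)
    codes <- matrix(sample(c(-2L, 0L, 0L, 0L, 2L), ng * ns, TRUE), ng, ns)
    p <- expr_cna_pair(vals, codes)
    z <- suppressMessages(compute_z(p$expr, p$cna, min_ref = 2))
    for (g in seq_len(ng)) {
      ref <- vals[g, codes[g, ] == 0L]
      if (length(ref) < 2 || sd(ref) == 0) {
        expect_true(all(is.na(z$z[g, ])))
      } else {
        expect_equal(unname(z$z[g, ]), (vals[g, ] - mean(ref)) / sd(ref),
                     tolerance = 1e-9)
        # reference standardization invariant
        zr <- z$z[g, codes[g, ] == 0L]
        expect_lt(abs(mean(zr)), 1e-9)
        expect_lt(abs(sd(zr) - 1), 1e-9)
      }
    }
  }
})

test_that("expression calls are invariant under positive affine rescaling", {
  set.seed(32)
  vals <- matrix(rlnorm(40, 4, 1), 4, 10)
  codes <- matrix(sample(c(0L, 0L, 0L, 2L), 40, TRUE), 4, 10)
  p <- expr_cna_pair(vals, codes)
  calls <- classify_expression(compute_z(p$expr, p$cna))
  p2 <- expr_cna_pair(vals * 3.7 + 11, codes)
  calls2 <- classify_expression(compute_z(p2$expr, p2$cna))
  expect_identical(calls, calls2)
  # threshold strictness
  expect_identical(unname(classify_expression(c(2.0001, -2.0001, -2, 2, NA))),
                   c("up", "down", "normal", "normal", "undefined"))
})

expr_fixture <- function(seed = 33, n_couples = 6, n_samples = 12) {
  set.seed(seed)
  rc <- random_cohort(n_couples, n_samples, with_expr = TRUE)
  al <- align_couples(rc$couples, rc$cohort)
  z <- suppressMessages(compute_z(rc$cohort$expr, rc$cohort$cna, min_ref = 2))
  list(rc = rc, al = al, calls = classify_expression(z))
}

test_that("per-sample expression rates match a nested-loop count", {
  fx <- expr_fixture()
  rates <- expression_rates(fx$calls, fx$al)
  cpl <- fx$al$couples
  want <- c(snorna_up = 0, snorna_down = 0, host_up = 0, host_down = 0)
  undef <- 0
  for (i in seq_len(nrow(cpl))) {
    for (j in seq_len(ncol(fx$calls))) {
      s <- fx$calls[cpl$snorna_id[i], j]
      h <- fx$calls[cpl$host_id[i], j]
      if (s == "up") want["snorna_up"] <- want["snorna_up"] + 1
      if (s == "down") want["snorna_down"] <- want["snorna_down"] + 1
      if (h == "up") want["host_up"] <- want["host_up"] + 1
      if (h == "down") want["host_down"] <- want["host_down"] + 1
      undef <- undef + (s == "undefined") + (h == "undefined")
    }
  }
  got <- setNames(rates$n_events, paste(rates$member, rates$direction, sep = "_"))
  expect_equal(got[names(want)], want)
  expect_equal(rates$rate_per_sample, rates$n_events / ncol(fx$calls))
  expect_equal(attr(rates, "n_undefined_cells"), undef)
})

test_that("a couple is up-regulated when either member is up, counted once", {
  calls <- rbind(SNO = c("up", "normal", "up", "normal"),
                 HG = c("up", "up", "normal", "normal"))
  colnames(calls) <- sprintf("S%d", 1:4)
  al <- structure(list(couples = data.frame(
    snorna_id = "SNO", snorna_symbol = "SNO", host_id = "HG",
    host_symbol = "HG", stringsAsFactors = FALSE),
    dropped = data.frame(), acronym = "T"), class = "aligned_couples")
  top <- top_k_upregulated(calls, al, k = 5)
  expect_equal(top$n_up, 3)           # S1 counts once despite both members up
  expect_equal(top$up_sample_fraction, 3 / 4)
  expect_identical(top$members, "both")
  # host-only couple keeps the member flag
  calls2 <- rbind(SNO = rep("normal", 10),
                  HG = c(rep("up", 3), rep("normal", 7)))
  colnames(calls2) <- sprintf("S%d", 1:10)
  top2 <- top_k_upregulated(calls2, al, k = 5)
  expect_equal(top2$up_sample_fraction, 0.3)
  expect_identical(top2$members, "host_only")
})

test_that("top up-regulated couples match the full-sort oracle", {
  fx <- expr_fixture(seed = 34, n_couples = 10, n_samples = 15)
  top <- top_k_upregulated(fx$calls, fx$al, k = 4)
  all_rows <- top_k_upregulated(fx$calls, fx$al, k = 1e6)
  want <- oracle_topk(all_rows, 4, "up_sample_fraction")
  expect_identical(top$key, want$key)
})

test_that("CNA/expression concordance handles empty denominators and matches set logic", {
  fx <- expr_fixture(seed = 35, n_couples = 8, n_samples = 14)
  conc <- cna_expression_concordance(fx$rc$cohort, fx$calls, fx$al, k = 3)
  codes <- unclass(fx$rc$cohort$cna)
  for (i in seq_len(nrow(conc))) {
    cpl <- fx$al$couples[match(conc$key[i], paste(fx$al$couples$snorna_id,
                                                  fx$al$couples$host_id, sep = "|")), ]
    amp <- up <- both <- 0
    for (j in colnames(fx$calls)) {
      is_amp <- isTRUE(codes[cpl$snorna_id, j] == 2L) || isTRUE(codes[cpl$host_id, j] == 2L)
      is_up <- fx$calls[cpl$snorna_id, j] == "up" || fx$calls[cpl$host_id, j] == "up"
      amp <- amp + is_amp; up <- up + is_up; both <- both + (is_amp && is_up)
    }
    expect_equal(conc$n_amplified[i], amp)
    expect_equal(conc$n_up[i], up)
    if (amp == 0) expect_true(is.na(conc$frac_amplified_up[i]))
    else expect_equal(conc$frac_amplified_up[i], both / amp)
  }
  expect_identical(attr(conc, "topk_overlap"),
                   length(intersect(attr(conc, "topk_cna"), attr(conc, "topk_expr"))))
})

test_that("dosage coupling raises the up-call rate among amplified cells", {
  # generator with a strong dosage effect and little noise: amplified cells
  # should be up-called far more often than diploid cells (module Fisher test)
  params <- generator_params(n_couples = 60, n_samples = 400, p_alt = 0.1,
                             p_co = 0.5, f_amp = 4, f_del = 0.25,
                             noise_sd = 0.1, p_shallow = 0, rng_seed = 99)
  sim <- generate_cohorts(params)
  coh <- sim$cohorts[[1]]
  calls <- classify_expression(compute_z(coh$expr, coh$cna))
  codes <- unclass(coh$cna)[rownames(calls), colnames(calls)]
  amp <- codes == 2L
  dip <- codes == 0L
  up <- calls == "up"
  tab <- c(sum(up & amp), sum(!up & amp), sum(up & dip), sum(!up & dip))
  p <- fisher_exact(tab[1], tab[2], tab[3], tab[4])
  expect_gt(mean(up[amp]), mean(up[dip]))
  expect_lt(p, 1e-3)
})
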