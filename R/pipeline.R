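#' Fit the full co-alteration analysis across cohorts
#'
#' The one-call interface: aligns the couple table to every cohort, runs the
#' copy-number co-alteration summaries, cross-cohort recurrence categories,
#' top-k rankings and per-couple association tests, and — for cohorts that
#' carry an expression matrix — diploid-referenced Z-scores, expression
#' calls, per-sample expression rates, top-k up-regulated couples and
#' CNA/expression concordance.
#'
#' @param cohorts named list of [cohort()] objects.
#' @param couples a `couple_set` from [build_couples()].
#' @param k top-k list size (default 10).
#' @param z_up,z_down expression-call thresholds (defaults +2/-2, strict).
#' @param min_ref minimum diploid reference size for Z-scores.
#' @param event_counting `"cell"` or `"gene"`, see [summarize_cohort()].
#' @return object of class `coalteration` with per-cohort components and the
#'   cross-cohort category table.
#' @export
coalteration <- function(cohorts, couples, k = 10L, z_up = 2, z_down = -2,
                         min_ref = 3L, event_counting = c("cell", "gene")) {
  event_counting <- match.arg(event_counting)
  stopifnot(length(cohorts) >= 1L)
  if (is.null(names(cohorts))) {
    names(cohorts) <- vapply(cohorts, `[[`, character(1L), "acronym")
  }
  per_cohort <- lapply(cohorts, function(coh) {
    aligned <- align_couples(couples, coh)
    summary <- summarize_cohort(coh, aligned, event_counting)
    assoc <- couple_association(coh, aligned)
    res <- list(aligned = aligned, summary = summary,
                top_cna = top_k_couples(summary, k), association = assoc)
    if (!is.null(coh$expr)) {
      z <- compute_z(coh$expr, coh$cna, min_ref)
      calls <- classify_expression(z, up = z_up, down = z_down)
      res$zscores <- z
      res$expr_rates <- expression_rates(calls, aligned, coh$acronym)
      res$top_expr <- top_k_upregulated(calls, aligned, k, coh$acronym)
      res$concordance <- cna_expression_concordance(coh, calls, aligned,
                                                    summary = summary, k = k)
    } else {
      sno_log("pipeline", sprintf("cohort %s has no expression matrix; expression stage skipped",
                                  coh$acronym), "warn")
    }
    res
  })
  summaries <- lapply(per_cohort, `[[`, "summary")
  categories <- cross_cohort_categories(summaries, couples)
  structure(list(per_cohort = per_cohort, categories = categories,
                 couples = couples, k = as.integer(k),
                 settings = list(z_up = z_up, z_down = z_down,
                                 min_ref = as.integer(min_ref),
                                 event_counting = event_counting)),
            class = "coalteration")
}

#' @export
print.coalteration <- function(x, ...) {
  cat(sprintf("<coalteration> %d cohort(s), %d couples\n",
              length(x$per_cohort), nrow(x$couples)))
  for (res in x$per_cohort) {
    s <- res$summary
    cat(sprintf("  %-8s n=%-5d cumulative CNA frequency %.4f%s\n",
                s$acronym, s$n_samples, s$cumulative_frequency,
                if (is.null(res$zscores)) " (no expression)" else ""))
  }
  pct <- attr(x$categories, "percentages")
  cat(sprintf("  couples: never %.1f%% | all %.1f%% | some %.1f%%\n",
              pct["never"], pct["all"], pct["some"]))
  invisible(x)
}

#' @export
summary.coalteration <- function(object, ...) {
  df <- do.call(rbind, lapply(object$per_cohort, function(res) {
    s <- res$summary
    data.frame(cohort = s$acronym, n_samples = s$n_samples,
               n_couples = s$n_couples,
               n_altered_cells = s$n_altered_cells,
               n_missing_cells = s$n_missing_cells,
               cumulative_frequency = s$cumulative_frequency,
               co_occurring_per_sample = unname(s$per_sample_rates["co_occurring"]),
               snorna_only_per_sample = unname(s$per_sample_rates["snorna_only"]),
               host_only_per_sample = unname(s$per_sample_rates["host_only"]),
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  structure(list(cohorts = df,
                 category_percentages = attr(object$categories, "percentages"),
                 n_not_evaluable = attr(object$categories, "n_not_evaluable")),
            class = "summary.coalteration")
}

#' @export
print.summary.coalteration <- function(x, ...) {
  print(x$cohorts)
  pct <- x$category_percentages
  cat(sprintf("categories: never %.1f%% | all %.1f%% | some %.1f%% (%d not evaluable)\n",
              pct["never"], pct["all"], pct["some"], x$n_not_evaluable))
  invisible(x)
}

#' Build a run configuration
#'
#' Collects all pipeline knobs with their defaults. `config` may be a YAML
#' file path or a named list; explicit arguments override it.
#'
#' @param config optional YAML path or named list.
#' @param ... overrides: `pairing` (path), `cohorts` (named list, each with
#'   `cna` and optional `expr` paths), `out_dir`, `k`, `z_up`, `z_down`,
#'   `min_ref`, `event_counting`, `seed`, `preset`, `n_samples`,
#'   `log_level`.
#' @return named list of class `run_config`.
#' @export
run_config <- function(config = NULL, ...) {
  defaults <- list(pairing = NULL, cohorts = NULL, out_dir = ".",
                   k = 10L, z_up = 2, z_down = -2, min_ref = 3L,
                   event_counting = "cell", seed = 1L, preset = NULL,
                   n_samples = 100L, log_level = "info")
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) defaults[names(config)] <- config
  extra <- list(...)
  defaults[names(extra)] <- extra
  if (defaults$k < 1L) stop("k must be >= 1")
  if (!defaults$event_counting %in% c("cell", "gene")) {
    stop("event_counting must be 'cell' or 'gene'")
  }
  structure(defaults, class = c("run_config", "list"))
}

#' Simulate a complete input set on disk
#'
#' Draws a synthetic pairing table plus cohorts (via a named preset or
#' default [generator_params()]) and writes every input file the pipeline
#' reads, along with the truth record (realized class counts, sign counts,
#' expression baselines) and the generator parameters.
#'
#' @param config a [run_config()]; uses `out_dir`, `seed`, `preset`,
#'   `n_samples`.
#' @return (invisibly) the config amended with the paths of the files
#'   written, ready to be passed to [cmd_run()].
#' @export
cmd_simulate <- function(config) {
  config <- run_config(config)
  old <- options(snohost.log_level = config$log_level); on.exit(options(old))
  params <- if (is.null(config$preset)) {
    generator_params(n_samples = config$n_samples, rng_seed = config$seed)
  } else {
    scenario_presets(config$preset, n_samples = config$n_samples,
                     rng_seed = config$seed)
  }
  sim <- generate_cohorts(params)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  write_pairing_table(sim$couples, p("pairing.tsv"))
  cohort_paths <- list()
  for (acr in names(sim$cohorts)) {
    coh <- sim$cohorts[[acr]]
    write_cna_matrix(coh$cna, p(sprintf("%s_cna.tsv", acr)))
    write_expr_matrix(coh$expr, p(sprintf("%s_expr.tsv", acr)))
    cohort_paths[[acr]] <- list(cna = p(sprintf("%s_cna.tsv", acr)),
                                expr = p(sprintf("%s_expr.tsv", acr)))
  }
  write_table(sim$truth$class_counts, p("truth_class_counts.tsv"))
  write_table(sim$truth$sign_counts, p("truth_sign_counts.tsv"))
  write_table(sim$truth$baselines, p("truth_baselines.tsv"))
  yaml::write_yaml(unclass(params), p("generator_params.yaml"))
  # a ready-to-use run configuration with paths relative to the output
  # directory, so the file is identical wherever the simulation lands
  rel_cohorts <- lapply(names(sim$cohorts), function(acr)
    list(cna = sprintf("%s_cna.tsv", acr), expr = sprintf("%s_expr.tsv", acr)))
  names(rel_cohorts) <- names(sim$cohorts)
  yaml::write_yaml(c(list(pairing = "pairing.tsv", cohorts = rel_cohorts),
                     config[c("k", "z_up", "z_down", "min_ref",
                              "event_counting", "seed", "n_samples")]),
                   p("config.yaml"))
  sno_log("simulate", sprintf("wrote %d cohort(s) to %s",
                              length(sim$cohorts), config$out_dir))
  config$pairing <- p("pairing.tsv")
  config$cohorts <- cohort_paths
  invisible(config)
}

#' Run the full pipeline on files and write every result table
#'
#' Reads the pairing table and per-cohort matrices named in the config,
#' fits [coalteration()], and writes one TSV per figure panel plus
#' per-cohort association, Z-score and concordance tables and a JSON run
#' manifest (package version, configuration, input checksums). Cohorts
#' without an expression matrix get the copy-number tables only.
#'
#' @param config a [run_config()] with `pairing` and `cohorts` set.
#' @return (invisibly) the fitted `coalteration` object.
#' @export
cmd_run <- function(config) {
  config <- run_config(config)
  old <- options(snohost.log_level = config$log_level); on.exit(options(old))
  if (is.null(config$pairing) || is.null(config$cohorts)) {
    stop("config must name a pairing table and at least one cohort")
  }
  # relative input paths are taken relative to out_dir (as written by
  # cmd_simulate's config.yaml)
  resolve <- function(f) {
    if (is.null(f) || file.exists(f)) f else file.path(config$out_dir, f)
  }
  couples <- read_pairing_table(resolve(config$pairing))
  cohorts <- lapply(names(config$cohorts), function(acr) {
    spec <- config$cohorts[[acr]]
    cna <- read_cna_matrix(resolve(spec$cna))
    expr_path <- resolve(spec$expr)
    expr <- if (!is.null(expr_path) && file.exists(expr_path)) {
      read_expr_matrix(expr_path)
    } else NULL
    cohort(acr, cna, expr)
  })
  names(cohorts) <- names(config$cohorts)
  fit <- coalteration(cohorts, couples, k = config$k, z_up = config$z_up,
                      z_down = config$z_down, min_ref = config$min_ref,
                      event_counting = config$event_counting)
  write_results(fit, config)
  invisible(fit)
}

# Writes every result table of a fitted coalteration object.
write_results <- function(fit, config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out, f)
  k <- fit$k

  cats <- fit$categories
  pct <- attr(cats, "percentages")
  write_table(cats, p("fig1a_categories.tsv"))

  f1b <- do.call(rbind, lapply(fit$per_cohort, function(res) {
    s <- res$summary
    data.frame(cohort = s$acronym, n_couples = s$n_couples,
               n_samples = s$n_samples, n_missing_cells = s$n_missing_cells,
               n_altered_cells = s$n_altered_cells,
               n_gene_events = s$n_gene_events,
               event_counting = s$event_counting,
               cumulative_frequency = s$cumulative_frequency,
               stringsAsFactors = FALSE)
  }))
  write_table(f1b, p("fig1b_cumulative_frequency.tsv"))

  f2a <- do.call(rbind, lapply(fit$per_cohort, function(res) {
    s <- res$summary
    tab <- table(factor(s$couples$couple_class,
                        levels = c("co_occurring", "altered_non_co", "absent")))
    n_mut <- sum(tab[c("co_occurring", "altered_non_co")])
    data.frame(cohort = s$acronym, couple_class = names(tab),
               n_couples = as.integer(tab),
               frac_of_all = as.integer(tab) / s$n_couples,
               frac_of_mutant = ifelse(names(tab) == "absent", NA_real_,
                                       ifelse(n_mut > 0, as.integer(tab) / n_mut,
                                              NA_real_)),
               stringsAsFactors = FALSE)
  }))
  write_table(f2a, p("fig2a_couple_cooccurrence.tsv"))

  f2b <- do.call(rbind, lapply(fit$per_cohort, function(res) {
    s <- res$summary
    data.frame(cohort = s$acronym,
               event_class = names(s$per_sample_rates),
               n_cells = as.integer(s$cell_counts[names(s$per_sample_rates)]),
               n_samples = s$n_samples,
               rate_per_sample = as.numeric(s$per_sample_rates),
               stringsAsFactors = FALSE)
  }))
  write_table(f2b, p("fig2b_per_sample_rates.tsv"))

  f2c <- do.call(rbind, lapply(fit$per_cohort, function(res) {
    s <- res$summary
    base <- data.frame(cohort = s$acronym,
                       context = rep(rownames(s$amp_del_counts), 2L),
                       sign = rep(c("amp", "del"), each = 3L),
                       n_events = c(s$amp_del_counts[, "amp"],
                                    s$amp_del_counts[, "del"]),
                       stringsAsFactors = FALSE)
    comp <- data.frame(cohort = s$acronym, context = "co_occurring_host",
                       sign = c("amp", "del"),
                       n_events = as.integer(s$host_co_signs),
                       stringsAsFactors = FALSE)
    rbind(base, comp)
  }))
  write_table(f2c, p("fig2c_amp_del.tsv"))

  for (res in fit$per_cohort) {
    acr <- res$summary$acronym
    write_table(res$top_cna, p(sprintf("fig3_top%d_%s.tsv", k, acr)))
    write_table(res$association, p(sprintf("association_%s.tsv", acr)))
    if (!is.null(res$zscores)) {
      zdf <- data.frame(gene_id = rownames(res$zscores$z),
                        reference_n = res$zscores$reference_n,
                        as.data.frame(res$zscores$z, check.names = FALSE),
                        check.names = FALSE, stringsAsFactors = FALSE)
      rownames(zdf) <- NULL
      write_table(zdf, p(sprintf("zscores_%s.tsv", acr)))
      write_table(res$top_expr, p(sprintf("fig4b_top%d_%s.tsv", k, acr)))
      conc <- res$concordance
      conc$cohort <- acr
      write_table(conc, p(sprintf("concordance_%s.tsv", acr)))
    }
  }

  with_expr <- Filter(function(res) !is.null(res$zscores), fit$per_cohort)
  if (length(with_expr) > 0L) {
    f4a <- do.call(rbind, lapply(with_expr, `[[`, "expr_rates"))
    rownames(f4a) <- NULL
    write_table(f4a, p("fig4a_expression_rates.tsv"))
  }

  inputs <- c(pairing = config$pairing,
              unlist(lapply(config$cohorts, function(x) unlist(x))))
  inputs <- inputs[file.exists(inputs)]
  checksums <- tools::md5sum(inputs)
  names(checksums) <- basename(inputs)  # keep the manifest path-independent
  manifest <- list(
    package = "snohost",
    version = as.character(utils::packageVersion("snohost")),
    settings = config[c("k", "z_up", "z_down", "min_ref", "event_counting")],
    category_percentages = as.list(pct),
    inputs = as.list(checksums))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(NULL)
}

#' Assemble a human-readable summary from a finished run
#'
#' Reads the result tables written by [cmd_run()] from `out_dir` and writes
#' `report.txt`: per-cohort headline numbers, the three cross-cohort
#' category percentages, and the top-k lists. Missing tables are an error
#' naming them.
#'
#' @param config a [run_config()] with `out_dir` set.
#' @return (invisibly) the path of the report written.
#' @export
cmd_report <- function(config) {
  config <- run_config(config)
  out <- config$out_dir
  p <- function(f) file.path(out, f)
  need <- c("fig1a_categories.tsv", "fig1b_cumulative_frequency.tsv",
            "fig2b_per_sample_rates.tsv")
  missing <- need[!file.exists(p(need))]
  if (length(missing) > 0L) {
    stop(sprintf("missing result table(s): %s", paste(missing, collapse = ", ")))
  }
  cats <- utils::read.delim(p("fig1a_categories.tsv"))
  f1b <- utils::read.delim(p("fig1b_cumulative_frequency.tsv"))
  evaluable <- cats$category != "not_evaluable"
  pct <- 100 * vapply(c("never", "all", "some"),
                      function(x) sum(cats$category[evaluable] == x),
                      numeric(1L)) / max(sum(evaluable), 1L)
  lines <- c("snoRNA/host gene co-alteration report", "")
  lines <- c(lines, sprintf(
    "couple categories: never %.1f%% | all %.1f%% | some %.1f%% (sum %.1f)",
    pct["never"], pct["all"], pct["some"], sum(pct)), "")
  for (i in seq_len(nrow(f1b))) {
    lines <- c(lines, sprintf(
      "%s: %d couples x %d samples, cumulative CNA frequency %.4f",
      f1b$cohort[i], f1b$n_couples[i], f1b$n_samples[i],
      f1b$cumulative_frequency[i]))
    topf <- p(sprintf("fig3_top%d_%s.tsv", config$k, f1b$cohort[i]))
    if (file.exists(topf)) {
      top <- utils::read.delim(topf)
      lines <- c(lines, sprintf("  top altered couples: %s",
                                paste(sprintf("%s (%.3f)", top$label,
                                              top$altered_sample_fraction),
                                      collapse = ", ")))
    }
  }
  report <- p("report.txt")
  writeLines(lines, report)
  invisible(report)
}
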