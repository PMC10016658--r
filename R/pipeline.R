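# End-to-end orchestration: simulate -> construct networks -> metrics
# -> group comparison -> behaviour correlation, with CSV/JSON exports
# and a human-readable report. A thin command-line wrapper over these
# functions ships in inst/cli/caninefc.R.

#' Simulate a cohort and write it to disk
#'
#' @param config a [cohort_config()].
#' @param dir output directory (created if missing).
#' @return The generated `fc_cohort`, invisibly.
#' @export
simulate_cohort <- function(config, dir) {
  cohort <- generate_cohort(config)
  write_cohort(cohort, dir)
  invisible(cohort)
}

#' Run the full analysis on a cohort
#'
#' Executes the analysis stages in order: subject-level network
#' construction and graph metrics across the density grid, the
#' three-level group comparison (global / nodal circuit / connection),
#' and the brain-behaviour Spearman correlations (when behaviour scores
#' are available). All stochastic stages (small-world null ensembles,
#' permutation nulls under ties) are governed by `seed`.
#'
#' @param cohort an `fc_cohort` (from [generate_cohort()] or
#'   [read_cohort()]), or a directory path readable by [read_cohort()].
#' @param grid a [density_grid()].
#' @param n_nulls rewired surrogates per density for small-worldness;
#'   0 skips sigma (and drops it from the global comparison).
#' @param seed integer seed.
#' @param mode Mann-Whitney mode, see [mann_whitney_u()].
#' @param include_homotopic test homotopic circuit connections at the
#'   connection level (default FALSE; the amygdala L-R strength is
#'   always available to the correlation stage).
#' @param fdr_scope FDR family for the correlation stage, see
#'   [correlate_features()].
#' @param out_dir optional directory: when given, all result tables are
#'   written as CSV plus a JSON summary of significant findings.
#' @return List of class `fc_results`: `metrics`, `edges`,
#'   `comparisons`, `correlations` (NULL without behaviour data),
#'   `seed`, `grid`.
#' @export
analyze_cohort <- function(cohort, grid = density_grid(), n_nulls = 0,
                           seed = 1, mode = "auto",
                           include_homotopic = FALSE,
                           fdr_scope = "strength", out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "fc_cohort"))
  atlas <- cohort$atlas
  metrics <- cohort_metrics(cohort$subjects, grid = grid, n_nulls = n_nulls,
                            seed = seed)
  edges <- edge_value_table(cohort$subjects, atlas, grid = grid,
                            include_homotopic = include_homotopic)
  comparisons <- run_three_level_comparison(metrics, edges, atlas,
                                            mode = mode, seed = seed + 7000L)
  correlations <- NULL
  if (!is.null(cohort$behavior) && nrow(cohort$behavior) > 0) {
    corr_edges <- edge_value_table(
      cohort$subjects[vapply(cohort$subjects, `[[`, character(1), "group") ==
                        "patient"],
      atlas, grid = grid, include_homotopic = TRUE)
    feats <- patient_feature_table(metrics, corr_edges, atlas)
    correlations <- correlate_features(feats, cohort$behavior,
                                       fdr_scope = fdr_scope)
  }
  res <- structure(
    list(metrics = metrics, edges = edges, comparisons = comparisons,
         correlations = correlations, seed = seed, grid = as.numeric(grid)),
    class = "fc_results")
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

#' Write analysis results to CSV and JSON
#'
#' @param results an `fc_results` object from [analyze_cohort()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "fc_results"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(metrics = file.path(dir, "metrics.csv"),
             edges = file.path(dir, "edges.csv"),
             comparisons = file.path(dir, "comparisons.csv"),
             summary = file.path(dir, "summary.json"))
  utils::write.csv(results$metrics, paths["metrics"], row.names = FALSE)
  utils::write.csv(results$edges, paths["edges"], row.names = FALSE)
  utils::write.csv(results$comparisons, paths["comparisons"],
                   row.names = FALSE)
  if (!is.null(results$correlations)) {
    paths["correlations"] <- file.path(dir, "correlations.csv")
    utils::write.csv(results$correlations, paths["correlations"],
                     row.names = FALSE)
  }
  sig <- results$comparisons[results$comparisons$p_fdr < 0.05, ]
  summary <- list(
    seed = results$seed,
    densities = results$grid,
    n_tests = nrow(results$comparisons),
    significant = if (nrow(sig) > 0) {
      lapply(seq_len(nrow(sig)), function(i) list(
        level = sig$level[i], target = sig$target[i], u = sig$u[i],
        p_fdr = sig$p_fdr[i],
        direction = ifelse(sig$direction[i] > 0, "hyper", "hypo")))
    } else list()
  )
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Human-readable summary report
#'
#' Tabulates the significant group comparisons (annotated hyper/hypo
#' for patient-versus-control direction) and, when present, the
#' significant behaviour correlations, as markdown text.
#'
#' @param results an `fc_results` object, or a directory written by
#'   [write_results()].
#' @param path optional file to write the report to.
#' @return Character vector of report lines, invisibly when `path` is
#'   given.
#' @export
write_report <- function(results, path = NULL) {
  if (is.character(results)) {
    comparisons <- utils::read.csv(file.path(results, "comparisons.csv"),
                                   stringsAsFactors = FALSE)
    cfile <- file.path(results, "correlations.csv")
    correlations <- if (file.exists(cfile)) {
      utils::read.csv(cfile, stringsAsFactors = FALSE)
    } else NULL
  } else {
    stopifnot(inherits(results, "fc_results"))
    comparisons <- results$comparisons
    correlations <- results$correlations
  }
  lines <- c("# Functional network analysis report", "")
  sig <- comparisons[!is.na(comparisons$p_fdr) & comparisons$p_fdr < 0.05, ]
  lines <- c(lines, "## Group comparisons (FDR < 0.05)", "")
  if (nrow(sig) == 0) {
    lines <- c(lines, "No significant findings.", "")
  } else {
    lines <- c(lines, "| level | target | U | p (FDR) | direction |",
               "|---|---|---|---|---|")
    for (i in seq_len(nrow(sig))) {
      lines <- c(lines, sprintf(
        "| %s | %s | %.1f | %.4f | %s |",
        sig$level[i], sig$target[i], sig$u[i], sig$p_fdr[i],
        ifelse(sig$direction[i] > 0, "hyper (patient > control)",
               "hypo (patient < control)")))
    }
    lines <- c(lines, "")
  }
  if (!is.null(correlations)) {
    csig <- correlations[correlations$computed &
                           ((!is.na(correlations$p_fdr) &
                               correlations$p_fdr < 0.05) |
                              (is.na(correlations$p_fdr) &
                                 correlations$p_raw < 0.05)), ]
    lines <- c(lines, "## Behaviour correlations (p < 0.05; strength family FDR-corrected)", "")
    if (nrow(csig) == 0) {
      lines <- c(lines, "No significant findings.", "")
    } else {
      lines <- c(lines, "| feature | scale | rho | p | n |",
                 "|---|---|---|---|---|")
      for (i in seq_len(nrow(csig))) {
        p <- if (!is.na(csig$p_fdr[i])) csig$p_fdr[i] else csig$p_raw[i]
        lines <- c(lines, sprintf("| %s | %s | %.3f | %.4f | %d |",
                                  csig$feature[i], csig$scale[i],
                                  csig$rho[i], p, csig$n_used[i]))
      }
      lines <- c(lines, "")
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
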