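#' Pipeline configuration
#'
#' Collects every setting of the end-to-end analysis. Either `registry`
#' (a path to a registry file) or `simulation` (a [sim_config()]) supplies
#' the input data.
#'
#' @param simulation a [sim_config()] used when no registry file is given.
#' @param registry optional path to a registry CSV.
#' @param min_count low-frequency code filter threshold (default 15).
#' @param level clustering unit, `"code"` or `"block"`.
#' @param k cluster count used with `selection_strategy = "manual"`.
#' @param selection_strategy passed to [select_k()].
#' @param k_range cluster counts evaluated in the selection report.
#' @param n_init,gap_B restarts for Lloyd's algorithm and reference draws for
#'   the gap statistic.
#' @param coverage_thresholds cumulative-coverage thresholds.
#' @param min_representation dominant-block threshold (default 0.75).
#' @param design_spec covariates for the ordinal model.
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param out_dir optional directory; when set, all stage outputs and a run
#'   manifest are written there.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            registry = NULL,
                            min_count = 15L,
                            level = c("code", "block"),
                            k = 4L,
                            selection_strategy = "manual",
                            k_range = 1:8,
                            n_init = 50L,
                            gap_B = 100L,
                            coverage_thresholds = c(0.6, 0.7, 0.8, 0.9, 1),
                            min_representation = 0.75,
                            design_spec = default_design_spec(),
                            seed = 1L,
                            out_dir = NULL) {
  level <- match.arg(level)
  structure(list(
    simulation = simulation, registry = registry,
    min_count = as.integer(min_count), level = level, k = as.integer(k),
    selection_strategy = selection_strategy, k_range = as.integer(k_range),
    n_init = as.integer(n_init), gap_B = as.integer(gap_B),
    coverage_thresholds = coverage_thresholds,
    min_representation = min_representation,
    design_spec = design_spec, seed = as.integer(seed), out_dir = out_dir
  ), class = "pipeline_config")
}

#' Run the full admission-risk stratification analysis
#'
#' Stages, in order: obtain the registry (simulate or read), preprocess
#' (impute, categorize, low-frequency filter), compute per-code (or
#' per-block) risks, build the cluster-count selection report and choose k,
#' cluster, propagate labels to presentations, summarize blocks with
#' cumulative coverage and dominant-block identification, build the heatmap
#' matrix, and fit the proportional-odds model of cluster membership.
#' Re-running with the same configuration and seed reproduces all numeric
#' outputs exactly.
#'
#' @param config a [pipeline_config()].
#' @return list of class `edrisk_run` with all stage outputs and a `manifest`
#'   of per-stage record counts (input = kept + excluded at every stage).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  manifest <- list(seed = seed, level = config$level,
                   min_count = config$min_count)

  # --- registry ---
  if (!is.null(config$registry)) {
    registry <- read_registry(config$registry)
    universe <- NULL
  } else {
    sim <- config$simulation
    sim$seed <- seed
    universe <- generate_code_universe(sim)
    registry <- generate_presentations(universe, sim)
  }
  manifest$n_raw <- nrow(registry)

  # --- preprocess ---
  prep <- preprocess_registry(registry, min_count = config$min_count)
  records <- prep$records
  manifest$n_dropped_no_diagnosis <- nrow(prep$dropped)
  manifest$n_excluded_low_frequency <- prep$filter_report$n_records_excluded
  manifest$n_analyzed <- nrow(records)
  stopifnot(manifest$n_raw ==
              manifest$n_dropped_no_diagnosis +
              manifest$n_excluded_low_frequency + manifest$n_analyzed)

  # --- risks & clustering ---
  risks <- if (config$level == "code") compute_code_risks(records) else
    compute_block_risks(records)
  values <- stats::setNames(risks$risk, risks$code)
  report <- cluster_selection_report(values, k_range = config$k_range,
                                     n_init = config$n_init,
                                     n_reference = config$gap_B,
                                     seed = seed + 1L)
  sel <- select_k(report, strategy = config$selection_strategy,
                  override = config$k)
  model <- report$models[[as.character(sel$k)]]
  risks$cluster <- unname(model$cluster[risks$code])

  clustered <- if (config$level == "code") {
    propagate_clusters(records, model)
  } else {
    rec <- records
    rec$block <- code_to_block(rec$icd10, icd10_blocks())
    rec$cluster <- unname(model$cluster[rec$block])
    rec
  }
  manifest$n_codes <- nrow(risks)
  manifest$cluster_sizes <- as.integer(table(clustered$cluster))

  # --- descriptives, blocks, coverage ---
  table1 <- descriptive_table(clustered)
  blocks <- icd10_blocks()
  bs <- summarize_blocks(clustered, blocks)
  coverage <- cumulative_coverage(bs, config$coverage_thresholds)
  dominant <- lapply(seq_len(sel$k), function(cl) {
    dominant_blocks(bs, config$min_representation, cluster = cl)
  })
  names(dominant) <- paste0("cluster_", seq_len(sel$k))
  heat <- heatmap_matrix(bs, blocks, coverage_threshold = 0.8)
  manifest$n_blocks <- nrow(bs$summary)

  # --- ordinal association ---
  design <- build_design(clustered, config$design_spec)
  fit <- fit_proportional_odds(design$X, design$y)
  forest <- forest_table(fit)

  run <- structure(list(
    config = config, universe = universe, registry = registry,
    records = clustered, filter_report = prep$filter_report,
    imputation_log = prep$imputation_log, risks = risks,
    selection = sel, model = model, table1 = table1,
    block_summary = bs, coverage = coverage, dominant = dominant,
    heatmap = heat, fit = fit, forest = forest, manifest = manifest
  ), class = "edrisk_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

# persist all stage outputs as delimited text / JSON
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(out_dir, f)
  utils::write.csv(run$risks, out("code_risks.csv"), row.names = FALSE)
  utils::write.csv(run$table1, out("table1.csv"), row.names = FALSE)
  utils::write.csv(run$coverage$ranked, out("coverage.csv"), row.names = FALSE)
  heat <- data.frame(block_id = rownames(run$heatmap),
                     chapter = attr(run$heatmap, "chapter"),
                     run$heatmap, row.names = NULL, check.names = FALSE)
  utils::write.csv(heat, out("heatmap_matrix.csv"), row.names = FALSE)
  utils::write.csv(run$forest, out("forest_table.csv"), row.names = FALSE)
  jsonlite::write_json(run$selection$report$summary,
                       out("selection_report.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(
    list(min_representation = run$config$min_representation,
         per_cluster = lapply(run$dominant, function(d) {
           list(n_blocks = nrow(d$blocks),
                n_presentations = d$n_presentations,
                share_pct = d$share_pct, blocks = d$blocks)
         })),
    out("dominant_blocks.json"), dataframe = "rows", auto_unbox = TRUE,
    digits = NA)
  jsonlite::write_json(
    list(thresholds = as.list(run$fit$thresholds),
         coefficients = as.list(run$fit$coefficients),
         se = as.list(run$fit$se),
         odds_ratios = as.list(run$fit$odds_ratios),
         ci95 = apply(run$fit$ci95, 1, as.list),
         log_likelihood = run$fit$log_likelihood,
         converged = run$fit$converged, n_used = run$fit$n_used),
    out("ordinal_fit.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(filter_report = unclass(run$filter_report)),
    out("filter_report.json"), auto_unbox = TRUE, digits = NA)
  manifest <- c(run$manifest,
                list(timestamp = format(Sys.time(), tz = "UTC"),
                     package_version = as.character(utils::packageVersion("edrisk")),
                     files = c("code_risks.csv", "table1.csv", "coverage.csv",
                               "heatmap_matrix.csv", "forest_table.csv",
                               "selection_report.json", "dominant_blocks.json",
                               "ordinal_fit.json", "filter_report.json")))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}

#' Per-cluster descriptive summary of presentation characteristics
#'
#' The cohort-description table: per cluster and overall, the size and its
#' percent of the total, the admission rate, counts and percents for each
#' categorical characteristic, and mean (SD) for continuous ones.
#' Percentages are reported to one decimal, half-up.
#'
#' @param records registry data frame with categories and a `cluster` column.
#' @return long-format data frame with columns `characteristic`, `level`,
#'   `group` (`"overall"` or the cluster label), `n`, `pct`, `mean`, `sd`.
#' @export
descriptive_table <- function(records) {
  stopifnot("cluster" %in% names(records))
  groups <- c(list(overall = records),
              split(records, paste0("cluster_", records$cluster)))
  cat_vars <- c("sex", "ethnicity", "cci_cat", "sbp_cat", "pulse_cat",
                "temp_cat")
  num_vars <- c("age", "prior_ed", "prior_inpt", "prior_surg", "prior_icu",
                "prior_hd", "prior_ica", "prior_infect")
  total <- nrow(records)
  rows <- list()
  for (g in names(groups)) {
    rec <- groups[[g]]
    n <- nrow(rec)
    rows[[length(rows) + 1]] <- data.frame(
      characteristic = "size", level = "", group = g, n = n,
      pct = round_half_up(100 * n / total, 1), mean = NA_real_, sd = NA_real_)
    rows[[length(rows) + 1]] <- data.frame(
      characteristic = "admission", level = "admitted", group = g,
      n = sum(rec$admitted),
      pct = round_half_up(100 * mean(rec$admitted), 1),
      mean = NA_real_, sd = NA_real_)
    for (v in cat_vars) {
      tab <- table(rec[[v]])
      rows[[length(rows) + 1]] <- data.frame(
        characteristic = v, level = names(tab), group = g,
        n = as.integer(tab), pct = round_half_up(100 * as.integer(tab) / n, 1),
        mean = NA_real_, sd = NA_real_)
    }
    for (v in num_vars) {
      rows[[length(rows) + 1]] <- data.frame(
        characteristic = v, level = "", group = g, n = n, pct = NA_real_,
        mean = round_half_up(mean(rec[[v]]), 1),
        sd = round_half_up(stats::sd(rec[[v]]), 1))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.edrisk_run <- function(x, ...) {
  m <- x$manifest
  cat("ED admission-risk stratification run\n")
  cat(sprintf("  presentations analyzed: %d (of %d raw; %d dropped, %d filtered)\n",
              m$n_analyzed, m$n_raw, m$n_dropped_no_diagnosis,
              m$n_excluded_low_frequency))
  cat(sprintf("  %s-level clustering: %d units, k = %d\n", m$level, m$n_codes,
              x$selection$k))
  rates <- vapply(split(x$records$admitted, x$records$cluster), mean, numeric(1))
  cat(sprintf("  cluster sizes: %s\n", paste(m$cluster_sizes, collapse = ", ")))
  cat(sprintf("  admission rates: %s\n",
              paste(sprintf("%.1f%%", 100 * rates), collapse = ", ")))
  invisible(x)
}
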