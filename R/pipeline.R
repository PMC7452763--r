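#' Pipeline configuration
#'
#' Bundles every stage's settings so a run is fully reproducible from its
#' logged configuration. Either `traces_paths`/`design_path` point at CSV
#' inputs, or (default) data are simulated from `simulation`.
#'
#' @param simulation An [simulation_config()] object (used when no input
#'   paths are given).
#' @param traces_paths Optional character vector of per-run trace CSVs.
#' @param design_path Optional design CSV path.
#' @param outdir Output directory.
#' @param clip `"after"` or `"before"`: negative-RFU clipping relative to
#'   within-bin averaging (see [merge_traces()]).
#' @param ci `"t"` or `"normal"` confidence intervals.
#' @param conf_level Confidence level for the bands.
#' @param hmw_threshold HMW boundary in bp.
#' @param min_size Lower AUC cutoff in bp.
#' @param gqn_threshold GQN-style score threshold in bp.
#' @param response ANOVA response: `"gqn"` or `"raw_pct"`.
#' @return List of class `epg_pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            traces_paths = NULL,
                            design_path = NULL,
                            outdir = tempfile("epg_run_"),
                            clip = "after",
                            ci = "t",
                            conf_level = 0.95,
                            hmw_threshold = 20000,
                            min_size = 250,
                            gqn_threshold = 10000,
                            response = c("gqn", "raw_pct")) {
  structure(
    list(simulation = simulation, traces_paths = traces_paths,
         design_path = design_path, outdir = outdir, clip = clip, ci = ci,
         conf_level = conf_level, hmw_threshold = hmw_threshold,
         min_size = min_size, gqn_threshold = gqn_threshold,
         response = match.arg(response)),
    class = "epg_pipeline_config"
  )
}

config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "outdir")])
}

write_stage_csv <- function(df, path, hash) {
  writeLines(paste0("# config_hash=", hash), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the full degradation-analysis pipeline
#'
#' simulate (or read) -> merge -> align -> group summaries -> HMW report
#' and scale factors -> GQN-style scores -> factorial ANOVA and the
#' full-vs-solution-only model comparison. All stage outputs are written
#' as tidy CSVs under `config$outdir`, each carrying the configuration
#' hash, alongside a JSON run manifest.
#'
#' @param config An [pipeline_config()] object.
#' @return Invisibly, a list with all stage results (`simulation` or
#'   inputs, `summaries_cell`, `summaries_solution`, `hmw_cell`,
#'   `hmw_solution`, `scale_factors`, `scores`, `anova_full`,
#'   `anova_solution`, `model_comparison`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "epg_pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)

  if (!is.null(config$traces_paths)) {
    if (is.null(config$design_path)) {
      stop("stage 'input': traces_paths given without design_path", call. = FALSE)
    }
    traces <- read_traces(config$traces_paths)
    design <- read_design(config$design_path)
    sim <- NULL
  } else {
    sim <- simulate_experiment(config$simulation)
    traces <- sim$traces
    design <- sim$design
  }
  rec <- reconcile_samples(traces, design)
  if (length(rec$traces_only) > 0 || length(rec$design_only) > 0) {
    stop("stage 'input': trace/design mismatch; traces without design: [",
         paste(rec$traces_only, collapse = ", "), "]; design without traces: [",
         paste(rec$design_only, collapse = ", "), "]", call. = FALSE)
  }

  merged <- merge_traces(traces, clip = config$clip)
  aligned <- align_runs(merged)

  summaries_cell <- summarize_group(
    aligned, design, group_by = c("solution", "heat", "temperature"),
    conf_level = config$conf_level, ci = config$ci)
  summaries_solution <- summarize_group(
    aligned, design, group_by = "solution",
    conf_level = config$conf_level, ci = config$ci)

  hmw_cell <- hmw_report(summaries_cell, hmw_threshold = config$hmw_threshold,
                         min_size = config$min_size)
  hmw_solution <- hmw_report(summaries_solution,
                             hmw_threshold = config$hmw_threshold,
                             min_size = config$min_size)
  sf <- scale_factors(hmw_solution)

  scores <- gqn_surrogate(traces, threshold = config$gqn_threshold,
                          min_size = config$min_size)
  if (config$response == "raw_pct") {
    persample <- traces |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(
        raw_pct = 100 * trace_auc(.data$size_bp, .data$rfu,
                                  lo = config$hmw_threshold) /
          trace_auc(.data$size_bp, .data$rfu, lo = config$min_size),
        .groups = "drop")
    scores <- dplyr::left_join(scores, persample, by = "sample_id")
  }
  anova_full <- factorial_anova(scores, design, terms = "full",
                                response = config$response)
  anova_solution <- factorial_anova(scores, design, terms = "solution",
                                    response = config$response)
  comparison <- compare_models(anova_full, anova_solution)

  manifest <- list(
    package = "epgtools",
    version = as.character(utils::packageVersion("epgtools")),
    config_hash = hash,
    seed = if (!is.null(sim)) config$simulation$seed else NA,
    n_samples = nrow(design),
    n_cells = design_balance(design)$n_cells,
    n_solution_groups = dplyr::n_distinct(design$solution),
    balanced = design_balance(design)$balanced,
    settings = config[c("clip", "ci", "conf_level", "hmw_threshold",
                        "min_size", "gqn_threshold", "response")]
  )

  anova_tab <- anova_full$table
  anova_tab_out <- rbind(
    data.frame(term = anova_tab$term, df = anova_tab$df, sumsq = anova_tab$sumsq,
               statistic = anova_tab$statistic, p_value = anova_tab$p_value,
               stars = anova_tab$stars),
    data.frame(term = "Residuals", df = anova_full$residual$df,
               sumsq = anova_full$residual$sumsq, statistic = NA, p_value = NA,
               stars = ""))

  out <- config$outdir
  write_stage_csv(summaries_cell, file.path(out, "summaries_cell.csv"), hash)
  write_stage_csv(summaries_solution, file.path(out, "summaries_solution.csv"), hash)
  write_stage_csv(hmw_cell, file.path(out, "hmw_report_cell.csv"), hash)
  write_stage_csv(hmw_solution, file.path(out, "hmw_report_solution.csv"), hash)
  write_stage_csv(format_scale_factors(sf), file.path(out, "scale_factors.csv"), hash)
  write_stage_csv(scores, file.path(out, "gqn_scores.csv"), hash)
  write_stage_csv(anova_tab_out, file.path(out, "anova_table.csv"), hash)
  write_stage_csv(comparison, file.path(out, "model_comparison.csv"), hash)
  # plot data: cell-level panels (treatment x time traces) and
  # solution-level panels, the layouts of the usual degradation figures
  write_stage_csv(summaries_cell, file.path(out, "plotdata_cells.csv"), hash)
  write_stage_csv(summaries_solution, file.path(out, "plotdata_solutions.csv"), hash)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(
    simulation = sim, design = design, merged = merged,
    summaries_cell = summaries_cell, summaries_solution = summaries_solution,
    hmw_cell = hmw_cell, hmw_solution = hmw_solution, scale_factors = sf,
    scores = scores, anova_full = anova_full, anova_solution = anova_solution,
    model_comparison = comparison, manifest = manifest
  ))
}
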