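#' End-to-end pipeline: ingest, diversity, turnover, intensification
#'
#' `run_pipeline()` sequences the whole analysis on one configuration and
#' writes every stage output as CSV, so a run is reproducible from the
#' configured seed alone.
#'
#' @name pipeline
NULL

#' Build a run configuration
#'
#' @param panel Either a district-level `crop_panel` or a path to a panel
#'   CSV. `NULL` (default) simulates a panel from `scenario`.
#' @param hierarchy A `region_hierarchy`, a path to a hierarchy CSV, or
#'   `NULL` when simulating.
#' @param scenario A [scenario_config()] used when `panel` is `NULL`.
#' @param t0_window,tend_window Analysis windows (must not overlap).
#' @param crop_sets Named list of RI crop sets (default [RI_CROP_SETS]).
#' @param baseline_crops Crop set for the declining-cereal baseline model.
#' @param impute_min Minimum observations for gap imputation.
#' @param adjust Use crop-count-adjusted diversity for the district series
#'   (the default, matching the convention that all sub-national diversity
#'   is reported adjusted; raw diversity is always computed and is what the
#'   country-level series uses).
#' @param target_n Crop count the adjustment extrapolates to.
#' @param reps Subsampling replicates per size for the adjustment.
#' @param alpha_level Significance threshold for trend classification.
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory (`NULL` for no files).
#' @return A list of class `run_config`.
#' @export
run_config <- function(panel = NULL, hierarchy = NULL,
                       scenario = scenario_config(),
                       t0_window = c(1956, 1960), tend_window = c(2004, 2008),
                       crop_sets = RI_CROP_SETS,
                       baseline_crops = c("sorghum", "millet"),
                       impute_min = 10L, adjust = TRUE, target_n = 83L,
                       reps = 200L, alpha_level = 0.05, seed = 42L,
                       out_dir = NULL) {
  if (max(t0_window) >= min(tend_window)) {
    stop("t0 and tend windows must not overlap", call. = FALSE)
  }
  structure(list(panel = panel, hierarchy = hierarchy, scenario = scenario,
                 t0_window = t0_window, tend_window = tend_window,
                 crop_sets = crop_sets, baseline_crops = baseline_crops,
                 impute_min = impute_min, adjust = adjust,
                 target_n = target_n, reps = reps,
                 alpha_level = alpha_level, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized keys mirror [run_config()] arguments; `scenario:` holds
#' [scenario_config()] arguments, `panel:`/`hierarchy:` are file paths.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  scen_args <- y$scenario %||% list()
  for (nm in c("base_yield", "yield_trend_a", "yield_trend_b")) {
    if (!is.null(scen_args[[nm]])) scen_args[[nm]] <- unlist(scen_args[[nm]])
  }
  scenario <- do.call(scenario_config, scen_args)
  args <- y[setdiff(names(y), "scenario")]
  if (!is.null(args$crop_sets)) args$crop_sets <- lapply(args$crop_sets, unlist)
  do.call(run_config, c(args, list(scenario = scenario)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Stages: (1) obtain the district panel (simulate, or read and validate),
#' (2) harmonize split districts to base boundaries and impute interior
#' gaps, (3) per-district diversity series plus the state- and country-level
#' (pooled) series and yearly beta diversity, with per-district temporal
#' trends,
#' (4) crop transition matrices between the two windows, (5) for each RI
#' crop set the district delta table and the AIC-selected model ladder,
#' plus the declining-cereal baseline model. All randomness derives from
#' `config$seed`; rerunning a configuration reproduces every output.
#'
#' @param config A [run_config()].
#' @return A list of class `run_report` with elements `diversity`,
#'   `state_diversity`, `country_diversity`, `beta`, `trends`, `transitions` (absolute and
#'   proportional), `delta_tables`, `ladders`, `baseline`, `counts`
#'   (record/district bookkeeping), `config`, and `files` (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  files <- character()

  # -- stage 1: ingest -------------------------------------------------------
  if (is.null(config$panel)) {
    scen <- config$scenario
    scen$seed <- config$seed
    sc <- generate_scenario(scen)
    panel <- sc$observed
    hierarchy <- sc$hierarchy
  } else {
    panel <- if (is.character(config$panel)) {
      read_panel(config$panel, level = "district")
    } else config$panel
    hierarchy <- if (is.character(config$hierarchy)) {
      read_hierarchy(config$hierarchy)
    } else config$hierarchy
    if (is.null(hierarchy)) {
      ids <- unique(panel$region_id)
      hierarchy <- region_hierarchy(stats::setNames(rep("S01", length(ids)), ids))
    }
  }
  n_obs_districts <- dplyr::n_distinct(panel$region_id)

  # -- stage 2: harmonize + impute ------------------------------------------
  panel <- harmonize_regions(panel, hierarchy)
  panel <- impute_gaps(panel, min_values = config$impute_min)
  n_base_districts <- dplyr::n_distinct(panel$region_id)

  # -- stage 3: diversity ----------------------------------------------------
  div <- diversity_table(panel, adjust = config$adjust,
                         target_n = config$target_n, reps = config$reps,
                         seed = config$seed)
  state <- aggregate_to_level(panel, hierarchy, target = "state")
  state_div <- diversity_table(state, adjust = config$adjust,
                               target_n = config$target_n, reps = config$reps,
                               seed = config$seed + 1L)
  country <- aggregate_to_level(panel, hierarchy, target = "country")
  country_div <- diversity_table(country, adjust = FALSE)
  beta <- beta_series(panel, diversity = div)
  trends <- div |>
    dplyr::group_by(.data$region_id) |>
    dplyr::group_modify(function(g, key) {
      diversity_trend(g$year, g$D, alpha_level = config$alpha_level)
    }) |>
    dplyr::ungroup()

  # -- stage 4: turnover -----------------------------------------------------
  pm <- align_period_means(period_mean_areas(panel, config$t0_window),
                           period_mean_areas(panel, config$tend_window))
  trans_abs <- transition_matrix(pm$t0, pm$tend, mode = "absolute")
  trans_prop <- transition_matrix(pm$t0, pm$tend, mode = "proportional")

  # -- stage 5: intensification ---------------------------------------------
  delta_tables <- lapply(config$crop_sets, function(cs) {
    build_delta_table(panel, div, cs, t0_window = config$t0_window,
                      tend_window = config$tend_window)
  })
  ladders <- lapply(delta_tables, fit_model_ladder, response = "delta_D")
  baseline_table <- build_delta_table(panel, div, config$baseline_crops,
                                      t0_window = config$t0_window,
                                      tend_window = config$tend_window)
  baseline <- sorghum_millet_baseline(baseline_table)

  counts <- list(
    observed_districts = n_obs_districts,
    base_districts = n_base_districts,
    records = nrow(panel),
    imputed = sum(panel$imputed),
    retained = vapply(delta_tables, nrow, integer(1)),
    dropped = vapply(delta_tables, function(t) length(attr(t, "dropped")),
                     integer(1))
  )
  report <- structure(list(
    diversity = div, state_diversity = state_div,
    country_diversity = country_div, beta = beta,
    trends = trends,
    transitions = list(absolute = trans_abs, proportional = trans_prop),
    delta_tables = delta_tables, ladders = ladders,
    baseline = baseline, baseline_table = baseline_table,
    counts = counts, config = config, files = files
  ), class = "run_report")

  if (!is.null(config$out_dir)) {
    report$files <- export_summary_tables(report, config$out_dir)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d base districts, %d records (%d imputed)\n",
              x$counts$base_districts, x$counts$records, x$counts$imputed))
  cat("selected models:\n")
  for (nm in names(x$ladders)) {
    cat("  ", nm, ": ", x$ladders[[nm]]$comparison$formula[x$ladders[[nm]]$selected],
        "\n", sep = "")
  }
  invisible(x)
}

#' Export the pipeline's summary tables
#'
#' Writes: a per-year district diversity summary (mean and 10th/90th
#' percentiles, linear-interpolation quantiles), the country diversity
#' series, the yearly beta series, per-district trends, both transition
#' matrices, each delta table, the model-comparison tables and the selected
#' model's coefficients, and a machine-readable run report (counts, seed).
#'
#' @param report A `run_report`.
#' @param out_dir Directory to write into (created if needed).
#' @return Named character vector of files written.
#' @export
export_summary_tables <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character()
  w <- function(x, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(x, p, progress = FALSE)
    files[[name]] <<- p
  }
  div_summary <- report$diversity |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      mean_D = mean(.data$D),
      p10_D = stats::quantile(.data$D, 0.10, type = 7, names = FALSE),
      p90_D = stats::quantile(.data$D, 0.90, type = 7, names = FALSE),
      n_regions = dplyr::n(), .groups = "drop"
    )
  w(div_summary, "diversity_district_summary.csv")
  w(report$diversity, "diversity_district.csv")
  w(report$state_diversity, "diversity_state.csv")
  w(report$country_diversity, "diversity_country.csv")
  w(report$beta, "beta_series.csv")
  w(report$trends, "diversity_trends.csv")
  write_transition_matrix(report$transitions$absolute,
                          file.path(out_dir, "transitions_absolute.csv"))
  files[["transitions_absolute.csv"]] <- file.path(out_dir, "transitions_absolute.csv")
  write_transition_matrix(report$transitions$proportional,
                          file.path(out_dir, "transitions_proportional.csv"))
  files[["transitions_proportional.csv"]] <- file.path(out_dir, "transitions_proportional.csv")
  for (nm in names(report$delta_tables)) {
    w(report$delta_tables[[nm]], paste0("delta_table_", nm, ".csv"))
    w(report$ladders[[nm]]$comparison, paste0("model_comparison_", nm, ".csv"))
    w(report$ladders[[nm]]$best$coefficients, paste0("model_selected_", nm, ".csv"))
  }
  w(report$baseline$coefficients, "baseline_sorghum_millet.csv")
  run_info <- tibble::tibble(
    key = c("seed", "observed_districts", "base_districts", "records",
            "imputed",
            paste0("retained_", names(report$counts$retained)),
            paste0("dropped_", names(report$counts$dropped))),
    value = c(report$config$seed, report$counts$observed_districts,
              report$counts$base_districts, report$counts$records,
              report$counts$imputed,
              unname(report$counts$retained), unname(report$counts$dropped))
  )
  w(run_info, "run_report.csv")
  files
}
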