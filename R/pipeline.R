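#' Read a pipeline configuration file
#'
#' Loads a YAML (or JSON) configuration and fills defaults. Recognized keys:
#' `simulation` (arguments for [sim_config()]; presence triggers simulation),
#' `input_dir` (read an existing cohort instead), `case_a` / `case_b`
#' (case labels compared between group a and group b), `group_a` / `group_b`,
#' `filter` (`low`, `high`), `grid` (`t_min`, `t_max`, `step`), `null_n`,
#' `seed`, `output_dir`.
#'
#' @param path Path to a YAML or JSON file.
#' @return A `nirs_pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param simulation List of [sim_config()] arguments, or `NULL` when
#'   reading data from `input_dir`.
#' @param input_dir Directory with `series.tsv` / `markers.tsv`.
#' @param group_a,group_b Group labels to compare.
#' @param case_a,case_b Case labels analyzed within each group.
#' @param filter List with band edges `low` and `high` (Hz).
#' @param grid List with `t_min`, `t_max`, `step`.
#' @param null_n Null-ensemble size per network.
#' @param seed Master seed.
#' @param output_dir Where [run_pipeline()] writes results.
#' @param ... Ignored extra keys (with a warning).
#' @export
pipeline_config <- function(simulation = list(), input_dir = NULL,
                            group_a = "spontaneous", group_b = "control",
                            case_a = "win-win", case_b = "win-win",
                            filter = list(low = 0.01, high = 0.3),
                            grid = list(t_min = 0.275, t_max = 0.625,
                                        step = 0.025),
                            null_n = 100, seed = 1L,
                            output_dir = "nirsnet-results", ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    warn(sprintf("Ignoring unknown config keys: %s.",
                 paste(names(extra), collapse = ", ")))
  }
  structure(list(simulation = simulation, input_dir = input_dir,
                 group_a = group_a, group_b = group_b,
                 case_a = case_a, case_b = case_b,
                 filter = filter, grid = grid,
                 null_n = null_n, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "nirs_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a two-group cohort, runs the per-subject threshold
#' sweep for the configured case pair, compares the groups, and writes the
#' results to the output directory: `sweep_comparison.csv` (tidy
#' per-threshold statistics), `subject_metrics_<group>.csv`,
#' `group_average_<group>.tsv` (average correlation matrices),
#' `bounds.csv` (threshold-grid diagnostics) and `provenance.json`
#' (configuration, seed, package version, timestamp).
#'
#' @param config A `nirs_pipeline_config` (see [pipeline_config()]).
#' @param out_dir Output directory; default from the config.
#' @return The `nirs_sweep` comparison, invisibly.
#' @export
run_pipeline <- function(config, out_dir = config$output_dir) {
  stopifnot(inherits(config, "nirs_pipeline_config"))
  if (!is.null(config$input_dir)) {
    cohort <- read_recordings(config$input_dir)
  } else {
    sim_args <- config$simulation
    sim_args$seed <- sim_args$seed %||% config$seed
    cohort <- simulate_cohort(do.call(sim_config, sim_args))
  }
  groups <- vapply(cohort, function(r) r$group, character(1))
  recs_a <- cohort[groups == config$group_a]
  recs_b <- cohort[groups == config$group_b]
  if (length(recs_a) == 0 || length(recs_b) == 0) {
    abort("Cohort does not contain both configured groups.")
  }
  grid <- threshold_grid(config$grid$t_min, config$grid$t_max,
                         config$grid$step)
  tab_a <- subject_metrics(recs_a, case = config$case_a, grid = grid,
                           null_n = config$null_n, seed = config$seed,
                           low = config$filter$low, high = config$filter$high)
  tab_b <- subject_metrics(recs_b, case = config$case_b, grid = grid,
                           null_n = config$null_n, seed = config$seed + 1L,
                           low = config$filter$low, high = config$filter$high)
  comparison <- compare_groups(tab_a, tab_b)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_csv(tidy(comparison), file.path(out_dir, "sweep_comparison.csv"))
  readr::write_csv(tab_a, file.path(out_dir,
    sprintf("subject_metrics_%s.csv", config$group_a)))
  readr::write_csv(tab_b, file.path(out_dir,
    sprintf("subject_metrics_%s.csv", config$group_b)))
  for (side in c("a", "b")) {
    recs <- if (side == "a") recs_a else recs_b
    case <- config[[paste0("case_", side)]]
    mats <- purrr::map(recs, function(r) {
      r |>
        nirs_bandpass(low = config$filter$low, high = config$filter$high) |>
        segment(case = case) |>
        normalize_and_average() |>
        pearson_matrix()
    })
    avg <- group_average(mats)
    write_matrix(avg, file.path(out_dir,
      sprintf("group_average_%s.tsv", config[[paste0("group_", side)]])))
    if (side == "a") {
      readr::write_csv(check_bounds(mats, grid = grid),
                       file.path(out_dir, "bounds.csv"))
    }
  }
  provenance <- list(
    package = "nirsnet",
    version = as.character(packageVersion("nirsnet")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = config$seed,
    config = unclass(config)
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(comparison)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
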