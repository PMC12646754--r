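#' Assemble a pipeline configuration
#'
#' Builds (and validates) the configuration driving [run_pipeline()], either
#' from arguments or from a YAML file with the same nesting. One master seed
#' governs every random draw; each stage derives its own named stream from
#' it so stages can be re-run in isolation reproducibly.
#'
#' @param seed Master integer seed.
#' @param output_dir Directory the pipeline writes into (created if needed).
#' @param plots_csv Optional existing plot table; when `NULL` the generator
#'   stage synthesizes one.
#' @param raster_dir Optional directory of per-plot rasters; when given, the
#'   metrics stage recomputes the structural metrics from them.
#' @param generator Named list passed to [generator_config()] (less `seed`).
#' @param metrics Named list: `threshold` (m), `quantile`.
#' @param model Named list: `k`, `grid_step` (yr), `reference_rainfall`,
#'   `reference_area`, `contrast_rainfall` (length 2, low/high).
#' @param validation Named list: `n_repetitions`, `n_classes`,
#'   `holdout_fraction`, `models` (`"full"`, `"single"`, `"pairs"` or
#'   `"all"`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, output_dir = tempfile("firecanopy_run_"),
                            plots_csv = NULL, raster_dir = NULL,
                            generator = list(), metrics = list(),
                            model = list(), validation = list()) {
  metrics <- utils::modifyList(list(threshold = 5, quantile = 0.98), metrics)
  model <- utils::modifyList(
    list(k = 10, grid_step = 1, reference_rainfall = 290,
         reference_area = 4.4, contrast_rainfall = c(260, 302)), model
  )
  validation <- utils::modifyList(
    list(n_repetitions = 50, n_classes = 11, holdout_fraction = 0.1,
         models = "full"), validation
  )
  if (!validation$models %in% c("full", "single", "pairs", "all")) {
    fc_abort("validation$models must be one of full, single, pairs, all",
             "firecanopy_bad_argument")
  }
  structure(
    list(seed = as.integer(seed), output_dir = output_dir,
         plots_csv = plots_csv, raster_dir = raster_dir,
         generator = generator, metrics = metrics, model = model,
         validation = validation),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    fc_abort(sprintf("config file '%s' does not exist", path),
             "firecanopy_io_error")
  }
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    fc_abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
             "firecanopy_stage_error")
  })
}

#' Run the full analysis pipeline
#'
#' Executes the stages end to end — simulate (unless an input table is
#' given), metrics (when rasters are given), fit-trajectories, validate —
#' and writes the plot table, per-metric fitted-curve CSVs and a single
#' machine-readable JSON report holding every headline statistic: peak ages
#' and values, mean decadal rates before/after the peak, rainfall contrasts
#' at the peak, adjusted R-squared per metric, hold-out RMSE/R-squared per
#' inverse model and the per-age-class bias table, plus the seeds and a
#' config echo. Outputs carry no timestamps, so a rerun with the same
#' config is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return The report, invisibly (also written to
#'   `<output_dir>/report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  plots <- run_stage("simulate", {
    if (is.null(config$plots_csv)) {
      gc_args <- utils::modifyList(config$generator, list(seed = config$seed))
      plots <- simulate_plot_table(trajectory_truth(), do.call(generator_config, gc_args))
      write_plot_table(plots, file.path(config$output_dir, "plots.csv"))
      plots
    } else {
      read_plot_table(config$plots_csv)
    }
  })

  if (!is.null(config$raster_dir)) {
    plots <- run_stage("metrics", {
      compute_plot_metrics(plots, config$raster_dir,
                           threshold = config$metrics$threshold,
                           q = config$metrics$quantile)
    })
  }

  trajectories <- run_stage("fit-trajectories", {
    out <- list()
    for (m in truth_metrics()) {
      fit <- fit_trajectory(plots, m, k = config$model$k)
      grid <- seq(ceiling(fit$age_range[1]), floor(fit$age_range[2]),
                  by = config$model$grid_step)
      curve <- predict_curve(fit, grid,
                             reference_rainfall = config$model$reference_rainfall,
                             reference_area = config$model$reference_area)
      rates <- rate_of_change(curve)
      kind <- if (m == "h_cv") "minimum" else "maximum"
      pk <- find_extremum(curve, kind)
      ct <- rainfall_contrast(fit, grid,
                              r_lo = config$model$contrast_rainfall[1],
                              r_hi = config$model$contrast_rainfall[2],
                              reference_area = config$model$reference_area,
                              kind = kind)
      readr::write_csv(
        dplyr::left_join(curve, rates, by = "age"),
        file.path(config$output_dir, sprintf("curve_%s.csv", m)),
        progress = FALSE
      )
      out[[m]] <- list(
        r2_adjusted = adjusted_r2(fit),
        peak_age = pk$peak_age, peak_value = pk$peak_value,
        extremum_kind = pk$kind, boundary = pk$boundary,
        mean_rate_before = pk$mean_rate_before,
        mean_rate_after = pk$mean_rate_after,
        rainfall_peak_difference = ct$peak_difference
      )
    }
    out
  })

  validation <- run_stage("validate", {
    suite <- model_suite()
    keep <- switch(config$validation$models,
      full = "full",
      single = c("h_max", "cover", "h_cv", "rumple_norm"),
      pairs = setdiff(names(suite), c("full", "h_max", "cover", "h_cv", "rumple_norm")),
      all = names(suite)
    )
    out <- list()
    for (nm in keep) {
      vr <- repeated_validation(
        plots, suite[[nm]],
        n_repetitions = config$validation$n_repetitions,
        n_classes = config$validation$n_classes,
        holdout_fraction = config$validation$holdout_fraction,
        seed = config$seed + 500000L,
        k = config$model$k
      )
      out[[nm]] <- list(
        rmse_mean = vr$rmse_mean, rmse_sd = vr$rmse_sd,
        r2_mean = vr$r2_mean, r2_sd = vr$r2_sd,
        n_repetitions = vr$n_repetitions, n_failed = vr$n_failed,
        class_bias = vr$class_bias
      )
    }
    out
  })

  report <- list(
    seed = config$seed,
    stage_seeds = list(generator = config$seed,
                       validation = config$seed + 500000L),
    n_plots = nrow(plots),
    trajectories = trajectories,
    validation = validation,
    config = config[c("metrics", "model", "validation")]
  )
  jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
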