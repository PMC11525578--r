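#' Pipeline configuration
#'
#' A single human-readable YAML file drives the whole pipeline; every field
#' has a default, and the exact configuration of a run is archived next to
#' its outputs so any artifact is reproducible from config + seed alone.
#'
#' Recognized sections (all optional): `output_dir`, `normalization`
#' (`t_min`, `t_max`), `esn` ([esn_config()] fields), `plan` (spans as
#' `[year, month]` pairs: `train_from`, `train_to`, `test_from`, `test_to`,
#' `scenario_from`, `scenario_to`; plus `ensemble_size`, `base_seed`),
#' `climate` ([synthetic_climate_spec()] fields except months/offset),
#' `response` ([synthetic_response_spec()] fields), and `paths`
#' (`reference_nc`, `plus2K_nc`, `plus4K_nc`, `mortality_csv`).
#'
#' @param path YAML file, or `NULL` for all defaults.
#' @param overrides named list merged over the file values (one level deep).
#' @return a list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- utils::modifyList(cfg, overrides)
  defaults <- list(
    output_dir = "esnmort-results",
    log_level = "info",
    normalization = list(t_min = -13, t_max = 47),
    esn = list(),
    plan = list(),
    climate = list(),
    response = list(),
    paths = list())
  cfg <- utils::modifyList(defaults, cfg)
  structure(cfg, class = "pipeline_config")
}

config_norm <- function(cfg) do.call(normalization_spec, cfg$normalization)

config_esn <- function(cfg) do.call(esn_config, cfg$esn)

config_plan <- function(cfg) {
  p <- cfg$plan
  args <- list()
  span <- function(a, b) list(from = unlist(a), to = unlist(b))
  if (!is.null(p$train_from)) args$train_span <- span(p$train_from, p$train_to)
  if (!is.null(p$test_from)) args$test_span <- span(p$test_from, p$test_to)
  if (!is.null(p$scenario_from)) {
    args$scenario_span <- span(p$scenario_from, p$scenario_to)
  }
  for (f in c("ensemble_size", "base_seed")) {
    if (!is.null(p[[f]])) args[[f]] <- p[[f]]
  }
  do.call(experiment_plan, args)
}

config_paths <- function(cfg) {
  utils::modifyList(
    list(reference_nc = file.path(cfg$output_dir, "t2m_reference.nc"),
         plus2K_nc = file.path(cfg$output_dir, "t2m_plus2K.nc"),
         plus4K_nc = file.path(cfg$output_dir, "t2m_plus4K.nc"),
         mortality_csv = file.path(cfg$output_dir, "mortality.csv"),
         ensemble_rds = file.path(cfg$output_dir, "ensemble.rds")),
    cfg$paths)
}

ensure_output_dir <- function(cfg) {
  if (!dir.exists(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE)
    pipeline_log(cfg, "created output directory %s", cfg$output_dir)
  }
  invisible(cfg$output_dir)
}

pipeline_log <- function(cfg, fmt, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible(NULL))
  message(sprintf(paste0("[esnmort] ", fmt), ...))
}

archive_config <- function(cfg, stem) {
  yaml::write_yaml(unclass(cfg), file.path(cfg$output_dir, paste0(stem, "-config.yaml")))
}

#' Simulate synthetic storyline fixtures
#'
#' Generates the reference, +2K and +4K synthetic temperature stacks (shared
#' seed, so the scenarios replay the same weather in a warmer climate) and
#' the matching synthetic mortality table, writing three netCDF files and
#' one CSV into the output directory. Byte-identical on rerun with the same
#' config.
#'
#' @param cfg a [read_pipeline_config()] object.
#' @return named list of written file paths, invisibly.
#' @export
cmd_simulate <- function(cfg = read_pipeline_config()) {
  ensure_output_dir(cfg)
  paths <- config_paths(cfg)
  plan <- config_plan(cfg)
  base_args <- cfg$climate
  base_args$months <- month_seq(plan$train_span$from, plan$test_span$to)

  # all three scenarios are generated over the full span with the same seed
  # (so the warmer worlds replay the same weather), then the warmer runs are
  # windowed to the scenario span, mirroring their shorter availability
  ref <- generate_temperature_series(
    do.call(synthetic_climate_spec, c(base_args, list(warming_offset = 0))))
  p2 <- window_temps(generate_temperature_series(
    do.call(synthetic_climate_spec, c(base_args, list(warming_offset = 2)))),
    plan$scenario_span$from, plan$scenario_span$to)
  p4 <- window_temps(generate_temperature_series(
    do.call(synthetic_climate_spec, c(base_args, list(warming_offset = 4)))),
    plan$scenario_span$from, plan$scenario_span$to)
  resp <- do.call(synthetic_response_spec, cfg$response)
  mort <- generate_mortality_series(ref, resp)

  write_temperature_nc(ref, paths$reference_nc)
  write_temperature_nc(p2, paths$plus2K_nc)
  write_temperature_nc(p4, paths$plus4K_nc)
  write_mortality_csv(mort, paths$mortality_csv)
  archive_config(cfg, "simulate")
  pipeline_log(cfg, "wrote %s, %s, %s, %s", paths$reference_nc, paths$plus2K_nc,
               paths$plus4K_nc, paths$mortality_csv)
  invisible(paths[c("reference_nc", "plus2K_nc", "plus4K_nc", "mortality_csv")])
}

#' Train the ensemble and evaluate the test period
#'
#' Reads the reference temperature stack and the mortality table, runs the
#' preprocessing chain (domain subset if configured, normalization,
#' flattening), trains the ensemble over the training span, evaluates the
#' test span, archives the trained ensemble, and writes a JSON summary
#' (RMS, relative RMS, ensemble SD range) plus a per-month prediction CSV.
#'
#' @param cfg a [read_pipeline_config()] object.
#' @return the `esn_ensemble`, invisibly.
#' @export
cmd_train_eval <- function(cfg = read_pipeline_config()) {
  ensure_output_dir(cfg)
  paths <- config_paths(cfg)
  plan <- config_plan(cfg)
  ref <- read_temperature_nc(paths$reference_nc)
  mort <- read_mortality_csv(paths$mortality_csv)
  res <- run_experiment(ref, mort, plan, config_esn(cfg),
                        norm = config_norm(cfg))
  ens <- res$ensemble
  save_ensemble(ens, paths$ensemble_rds, lat = ref$lat, lon = ref$lon)

  summary <- list(rms = ens$rms, rms_relative_pct = ens$rms_relative,
                  member_rms = ens$member_rms,
                  ensemble_size = plan$ensemble_size,
                  test_sd_range = range(ens$test$sd))
  jsonlite::write_json(summary, file.path(cfg$output_dir, "train_eval.json"),
                       auto_unbox = TRUE, digits = NA)
  pred <- data.frame(ens$test$months, mean = ens$test$mean, sd = ens$test$sd,
                     target = ens$targets_test)
  utils::write.csv(pred, file.path(cfg$output_dir, "test_predictions.csv"),
                   row.names = FALSE)
  archive_config(cfg, "train_eval")
  pipeline_log(cfg, "test RMS %.3g (%.2f%% of mean target)", ens$rms,
               ens$rms_relative)
  invisible(ens)
}

#' Predict mortality under the warmer-world scenarios
#'
#' Loads the archived trained ensemble, drives each member with the +2K and
#' +4K temperature stacks over the scenario span, and writes the comparison
#' bundle: per-scenario monthly CSV (mean, SD, reference rate, difference,
#' absolute deaths) and a JSON of seasonal aggregates.
#'
#' @param cfg a [read_pipeline_config()] object.
#' @return named list of `scenario_comparison` objects, invisibly.
#' @export
cmd_predict_scenarios <- function(cfg = read_pipeline_config()) {
  ensure_output_dir(cfg)
  paths <- config_paths(cfg)
  plan <- config_plan(cfg)
  if (!file.exists(paths$ensemble_rds)) {
    stop(sprintf("missing trained-ensemble archive %s; run cmd_train_eval() first",
                 paths$ensemble_rds), call. = FALSE)
  }
  ens <- load_ensemble(paths$ensemble_rds)
  norm <- config_norm(cfg)
  mort <- read_mortality_csv(paths$mortality_csv)

  comparisons <- list()
  for (s in c("plus2K", "plus4K")) {
    nc <- paths[[paste0(s, "_nc")]]
    if (!file.exists(nc)) next
    temps <- window_temps(read_temperature_nc(nc),
                          plan$scenario_span$from, plan$scenario_span$to)
    if (!is.null(ens$lat) &&
        !(isTRUE(all.equal(temps$lat, ens$lat)) &&
          isTRUE(all.equal(temps$lon, ens$lon)))) {
      stop(sprintf("grid of %s does not match the training grid", nc), call. = FALSE)
    }
    u <- flatten_inputs(normalize_temperature(temps, norm))
    pred <- predict_ensemble(ens, u)
    comparisons[[s]] <- compare_scenarios(pred, mort, plan)
  }
  if (length(comparisons) == 0L) stop("no scenario input files found", call. = FALSE)

  write_comparison_csv(comparisons, file.path(cfg$output_dir, "scenario_comparison.csv"))
  agg <- lapply(comparisons, function(x)
    list(summer_mean_diff = x$summer_mean_diff,
         winter_mean_diff = x$winter_mean_diff,
         summer_mean_absolute_deaths = x$summer_mean_absolute_deaths))
  jsonlite::write_json(agg, file.path(cfg$output_dir, "scenario_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  archive_config(cfg, "predict_scenarios")
  for (s in names(comparisons)) {
    pipeline_log(cfg, "%s: summer diff %+.2f per 100,000, winter diff %+.2f", s,
                 comparisons[[s]]$summer_mean_diff,
                 comparisons[[s]]$winter_mean_diff)
  }
  invisible(comparisons)
}

#' Plot the scenario comparison bundle
#'
#' Reads `scenario_comparison.csv` from the output directory and writes a
#' PNG time-series figure of the monthly differences per scenario, with the
#' ensemble-SD band shaded.
#'
#' @param cfg a [read_pipeline_config()] object.
#' @return the PNG path, invisibly.
#' @export
cmd_report <- function(cfg = read_pipeline_config()) {
  path <- file.path(cfg$output_dir, "scenario_comparison.csv")
  if (!file.exists(path)) stop("run cmd_predict_scenarios() first", call. = FALSE)
  df <- utils::read.csv(path)
  png_path <- file.path(cfg$output_dir, "scenario_diff.png")
  grDevices::png(png_path, width = 900, height = 500)
  on.exit(grDevices::dev.off(), add = TRUE)
  tnum <- df$year + (df$month - 0.5) / 12
  cols <- c(plus2K = "firebrick", plus4K = "steelblue")
  plot(range(tnum), range(df$diff - df$scenario_sd, df$diff + df$scenario_sd),
       type = "n", xlab = "year",
       ylab = "rate difference (per 100,000/month)",
       main = "Scenario minus reference mortality rate")
  abline(h = 0, col = "grey60")
  for (s in unique(df$scenario)) {
    d <- df[df$scenario == s, ]
    tn <- tnum[df$scenario == s]
    grDevices::adjustcolor(cols[[s]], alpha.f = 0.25) |>
      (\(cc) graphics::polygon(c(tn, rev(tn)),
                               c(d$diff - d$scenario_sd,
                                 rev(d$diff + d$scenario_sd)),
                               border = NA, col = cc))()
    graphics::lines(tn, d$diff, col = cols[[s]], lwd = 2)
    graphics::points(tn, d$diff, col = cols[[s]], pch = 16, cex = 0.7)
  }
  graphics::legend("topleft", legend = unique(df$scenario),
                   col = cols[unique(df$scenario)], lwd = 2, bty = "n")
  pipeline_log(cfg, "wrote %s", png_path)
  invisible(png_path)
}
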