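#' Experiment protocol plan
#'
#' The train/test/scenario protocol: training on Jan 2015 - May 2019
#' (53 months), testing on the following Jun - Dec 2019 (7 months), scenario
#' predictions over Jan 2017 - Dec 2019, a 25-member ensemble, and
#' June-August as the summer aggregate (December-February as the symmetric
#' winter aggregate). Spans extending into 2020 or later trigger a warning:
#' the protocol deliberately stops before 2020 to exclude pandemic excess
#' mortality.
#'
#' @param train_span,test_span,scenario_span lists with `from` and `to`
#'   elements, each `c(year, month)` inclusive.
#' @param ensemble_size number of independently initialized networks.
#' @param base_seed integer; member i uses seed `base_seed + i`.
#' @param summer_months,winter_months integer month sets for the seasonal
#'   aggregates.
#' @return an object of class `experiment_plan`.
#' @export
experiment_plan <- function(train_span = list(from = c(2015, 1), to = c(2019, 5)),
                            test_span = list(from = c(2019, 6), to = c(2019, 12)),
                            scenario_span = list(from = c(2017, 1), to = c(2019, 12)),
                            ensemble_size = 25L, base_seed = 1L,
                            summer_months = 6:8,
                            winter_months = c(12L, 1L, 2L)) {
  if (ensemble_size < 1L) stop("ensemble_size must be >= 1", call. = FALSE)
  for (span in list(train_span, test_span, scenario_span)) {
    if (month_index(span$to[1], span$to[2]) < month_index(span$from[1], span$from[2])) {
      stop("span end precedes its start", call. = FALSE)
    }
    if (span$to[1] >= 2020) {
      warning("span extends into 2020+; the protocol excludes the pandemic years",
              call. = FALSE)
    }
  }
  structure(list(train_span = train_span, test_span = test_span,
                 scenario_span = scenario_span,
                 ensemble_size = as.integer(ensemble_size),
                 base_seed = as.integer(base_seed),
                 summer_months = as.integer(summer_months),
                 winter_months = as.integer(winter_months)),
            class = "experiment_plan")
}

#' Chronological train/test split
#'
#' Returns the indices of the training and test months within a monthly
#' series. The two spans must be disjoint, chronological, and contiguous
#' (the test period starts the month after training ends) so that the
#' reservoir state can continue from the end of the training run.
#'
#' @param months data.frame of `year`, `month` rows describing the series.
#' @param plan an [experiment_plan()].
#' @return list with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(months, plan) {
  stopifnot(inherits(plan, "experiment_plan"))
  idx <- month_index(months$year, months$month)
  tr0 <- month_index(plan$train_span$from[1], plan$train_span$from[2])
  tr1 <- month_index(plan$train_span$to[1], plan$train_span$to[2])
  te0 <- month_index(plan$test_span$from[1], plan$test_span$from[2])
  te1 <- month_index(plan$test_span$to[1], plan$test_span$to[2])
  if (te0 <= tr1) stop("train and test spans overlap (or are swapped)", call. = FALSE)
  if (te0 != tr1 + 1L) {
    stop("gap between training and test spans; the stream must be contiguous",
         call. = FALSE)
  }
  train <- which(idx >= tr0 & idx <= tr1)
  test <- which(idx >= te0 & idx <= te1)
  if (length(train) != tr1 - tr0 + 1L || length(test) != te1 - te0 + 1L) {
    stop("series does not cover the requested train/test spans", call. = FALSE)
  }
  list(train = train, test = test)
}

#' Per-month ensemble prediction summary
#'
#' @param members numeric matrix, months x ensemble members.
#' @param months data.frame of `year`, `month` rows for the rows of
#'   `members`.
#' @return object of class `ensemble_prediction` with elements `members`,
#'   `months`, `mean` (arithmetic mean across members) and `sd` (per-month
#'   standard deviation across members; 0 for a single member).
#' @export
ensemble_prediction <- function(members, months) {
  members <- as.matrix(members)
  stopifnot(nrow(members) == nrow(months))
  s <- if (ncol(members) > 1L) apply(members, 1L, stats::sd) else rep(0, nrow(members))
  structure(list(members = members, months = as.data.frame(months),
                 mean = rowMeans(members), sd = s),
            class = "ensemble_prediction")
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  cat(sprintf("<ensemble_prediction> %d members, %d months, SD range [%.3g, %.3g]\n",
              ncol(x$members), nrow(x$members), min(x$sd), max(x$sd)))
  invisible(x)
}

#' Train and evaluate an ensemble of echo state networks
#'
#' Trains `plan$ensemble_size` networks that differ only in their
#' initialization seed (`base_seed + member index`); the training data are
#' never resampled. Each member runs the reservoir over the contiguous
#' train+test input stream once, fits the readout on the training months
#' (after the washout), and predicts the test months from the continued
#' reservoir state. Scenario input sequences, which are not temporally
#' contiguous with the training stream, are run from a zero initial state.
#' Members are independent, so the result does not depend on execution
#' order.
#'
#' @param plan an [experiment_plan()].
#' @param inputs `K x T` normalized input matrix covering the train and test
#'   spans (columns in month order).
#' @param targets numeric rate vector of length T aligned with `inputs`.
#' @param config an [esn_config()]; its `seed` is overridden per member.
#' @param months data.frame of `year`, `month` for the input columns; if
#'   `NULL`, parsed from "YYYY-MM" column names.
#' @param scenario_inputs named list of `K x T_s` matrices (same flattening
#'   order) to predict with each trained member, e.g.
#'   `list(plus2K = ..., plus4K = ...)`.
#' @param scenario_months data.frame of months for the scenario columns
#'   (shared by all scenarios); parsed from column names when `NULL`.
#' @return object of class `esn_ensemble`: `test`, `train` and
#'   `scenarios$<name>` are [ensemble_prediction()]s; `rms` / `rms_relative`
#'   give the test-period error of the ensemble-mean prediction and
#'   `member_rms` the per-member errors.
#' @export
run_ensemble <- function(plan, inputs, targets, config = esn_config(),
                         months = NULL, scenario_inputs = list(),
                         scenario_months = NULL) {
  stopifnot(inherits(plan, "experiment_plan"), inherits(config, "esn_config"))
  inputs <- as.matrix(inputs)
  if (is.null(months)) months <- parse_month_colnames(inputs)
  if (length(targets) != ncol(inputs)) {
    stop("targets must align with input columns", call. = FALSE)
  }
  if (length(scenario_inputs) > 0 && is.null(scenario_months)) {
    scenario_months <- parse_month_colnames(scenario_inputs[[1]])
  }
  split <- split_train_test(months, plan)
  k <- nrow(inputs)
  m <- plan$ensemble_size

  test_pred <- matrix(NA_real_, length(split$test), m)
  train_pred <- matrix(NA_real_, length(split$train), m)
  scen_pred <- lapply(scenario_inputs, function(s)
    matrix(NA_real_, ncol(as.matrix(s)), m))
  member_rms <- numeric(m)
  seeds <- plan$base_seed + seq_len(m)
  readouts <- vector("list", m)

  for (i in seq_len(m)) {
    cfg <- config
    cfg$seed <- seeds[i]
    net <- init_esn(cfg, k)
    states <- run_reservoir(net, inputs)
    net <- train_readout(net,
                         inputs[, split$train, drop = FALSE],
                         states[, split$train, drop = FALSE],
                         targets[split$train])
    d_all <- rbind(1, inputs, states)
    y_all <- as.vector(net$W_out %*% d_all)
    train_pred[, i] <- y_all[split$train]
    test_pred[, i] <- y_all[split$test]
    member_rms[i] <- rms_error(y_all[split$test], targets[split$test])$rms
    readouts[[i]] <- net$W_out
    for (s in names(scenario_inputs)) {
      scen_pred[[s]][, i] <- as.vector(predict(net, scenario_inputs[[s]]))
    }
  }

  test_ens <- ensemble_prediction(test_pred, months[split$test, , drop = FALSE])
  err <- rms_error(test_ens$mean, targets[split$test])
  structure(list(
    plan = plan, config = config,
    train = ensemble_prediction(train_pred, months[split$train, , drop = FALSE]),
    test = test_ens,
    targets_train = targets[split$train], targets_test = targets[split$test],
    rms = err$rms, rms_relative = err$rms_relative, member_rms = member_rms,
    seeds = seeds, input_dim = k, readouts = readouts,
    scenarios = lapply(scen_pred, ensemble_prediction,
                       months = scenario_months)),
    class = "esn_ensemble")
}

#' @export
print.esn_ensemble <- function(x, ...) {
  cat(sprintf(
    "<esn_ensemble> %d members; test RMS %.3g (%.2f%% of mean target); scenarios: %s\n",
    x$plan$ensemble_size, x$rms, x$rms_relative,
    if (length(x$scenarios)) paste(names(x$scenarios), collapse = ", ") else "none"))
  invisible(x)
}

parse_month_colnames <- function(m) {
  cn <- colnames(as.matrix(m))
  if (is.null(cn) || !all(grepl("^\\d{4}-\\d{2}$", cn))) {
    stop("months not given and column names are not 'YYYY-MM' labels", call. = FALSE)
  }
  data.frame(year = as.integer(substr(cn, 1, 4)),
             month = as.integer(substr(cn, 6, 7)))
}

#' Scenario-minus-reference mortality comparison
#'
#' Differences between a scenario's ensemble-mean predicted rates and the
#' observed (reference) rates for the matching calendar months, with
#' June-August and December-February aggregates and the conversion of rate
#' differences to absolute additional deaths per month,
#' `diff * population / 1e5`.
#'
#' @param ens an [ensemble_prediction()] for one scenario (months attached).
#' @param reference a [mortality_series()] covering the scenario months; its
#'   rates are the reference and its population drives the absolute-death
#'   conversion.
#' @param plan an [experiment_plan()] (for the seasonal month sets).
#' @param population optional monthly population overriding the reference
#'   series' column (scalar or per-month vector).
#' @return object of class `scenario_comparison`: a `monthly` data.frame
#'   (`year`, `month`, `scenario_mean`, `scenario_sd`, `reference_rate`,
#'   `diff`, `absolute_deaths`) plus `summer_mean_diff`, `winter_mean_diff`,
#'   `summer_mean_absolute_deaths`.
#' @export
compare_scenarios <- function(ens, reference, plan = experiment_plan(),
                              population = NULL) {
  stopifnot(inherits(ens, "ensemble_prediction"),
            inherits(reference, "mortality_series"))
  em <- month_index(ens$months$year, ens$months$month)
  rm_ <- month_index(reference$year, reference$month)
  pos <- match(em, rm_)
  if (anyNA(pos)) {
    stop("reference series does not cover all scenario months", call. = FALSE)
  }
  ref_rate <- reference$rate[pos]
  pop <- if (is.null(population)) reference$population[pos]
         else rep_len(population, length(em))
  diff <- ens$mean - ref_rate
  abs_deaths <- diff * pop / 1e5
  monthly <- data.frame(year = ens$months$year, month = ens$months$month,
                        scenario_mean = ens$mean, scenario_sd = ens$sd,
                        reference_rate = ref_rate, diff = diff,
                        absolute_deaths = abs_deaths)
  in_summer <- monthly$month %in% plan$summer_months
  in_winter <- monthly$month %in% plan$winter_months
  structure(list(
    monthly = monthly,
    summer_mean_diff = mean(diff[in_summer]),
    winter_mean_diff = mean(diff[in_winter]),
    summer_mean_absolute_deaths = mean(abs_deaths[in_summer])),
    class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf(paste0(
    "<scenario_comparison> %d months; summer (Jun-Aug) mean diff %+.2f per 100,000",
    " (~%+.0f deaths/month); winter mean diff %+.2f\n"),
    nrow(x$monthly), x$summer_mean_diff, x$summer_mean_absolute_deaths,
    x$winter_mean_diff))
  invisible(x)
}

#' End-to-end experiment from series objects
#'
#' Convenience wrapper over the full protocol: normalizes and flattens the
#' reference and scenario temperature series (checking they share one grid),
#' aligns the mortality targets, trains the ensemble, and compares each
#' scenario against the observed rates over the scenario span.
#'
#' @param ref_temps reference-scenario [temperature_field_series()] in degC
#'   covering the train and test spans.
#' @param mortality a [mortality_series()] covering the same span.
#' @param plan an [experiment_plan()].
#' @param config an [esn_config()].
#' @param scenario_temps named list of warmer-world series on the same grid,
#'   covering the scenario span.
#' @param norm a [normalization_spec()].
#' @return list with the `esn_ensemble` (`$ensemble`) and one
#'   `scenario_comparison` per scenario (`$comparisons`).
#' @export
run_experiment <- function(ref_temps, mortality, plan = experiment_plan(),
                           config = esn_config(),
                           scenario_temps = list(),
                           norm = normalization_spec()) {
  stopifnot(inherits(ref_temps, "temp_field_series"),
            inherits(mortality, "mortality_series"))
  for (s in scenario_temps) assert_same_grid(ref_temps, s)

  span_from <- plan$train_span$from; span_to <- plan$test_span$to
  u_ref <- flatten_inputs(normalize_temperature(window_temps(ref_temps, span_from, span_to), norm))
  mort <- window_mortality(mortality, span_from, span_to)
  months <- data.frame(year = mort$year, month = mort$month)

  scen_u <- lapply(scenario_temps, function(s) {
    flatten_inputs(normalize_temperature(
      window_temps(s, plan$scenario_span$from, plan$scenario_span$to), norm))
  })
  ens <- run_ensemble(plan, u_ref, mort$rate, config, months = months,
                      scenario_inputs = scen_u)
  comparisons <- lapply(ens$scenarios, compare_scenarios,
                        reference = mortality, plan = plan)
  list(ensemble = ens, comparisons = comparisons)
}

#' Archive / restore a trained ensemble
#'
#' The archive (RDS, schema version 1) stores the configuration, the member
#' seeds, the trained readout matrices and the grid axes defining the
#' flattening order. The large fixed random matrices are *not* stored: they
#' are bit-identical functions of config + seed and are regenerated by
#' [predict_ensemble()], keeping the archive a few hundred kilobytes instead
#' of gigabytes.
#'
#' @param ens an `esn_ensemble` from [run_ensemble()].
#' @param path archive path.
#' @param lat,lon grid axes recording the flattening order.
#' @return `path` invisibly; `load_ensemble()` returns the archive list.
#' @export
save_ensemble <- function(ens, path, lat = NULL, lon = NULL) {
  stopifnot(inherits(ens, "esn_ensemble"))
  saveRDS(list(schema = "esnmort/ensemble", schema_version = 1L,
               config = ens$config, plan = ens$plan, seeds = ens$seeds,
               input_dim = ens$input_dim, readouts = ens$readouts,
               lat = lat, lon = lon),
          path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "esnmort/ensemble")) {
    stop("not an esnmort ensemble archive", call. = FALSE)
  }
  obj
}

#' Predict with every member of a trained ensemble
#'
#' Regenerates each member's fixed weights from its seed, installs the
#' archived readout, and predicts over the inputs from a zero initial state.
#'
#' @param ens an `esn_ensemble` or an archive from [load_ensemble()].
#' @param inputs `K x T` normalized input matrix in the training flattening
#'   order.
#' @param months data.frame of months for the columns; parsed from column
#'   names when `NULL`.
#' @return an [ensemble_prediction()].
#' @export
predict_ensemble <- function(ens, inputs, months = NULL) {
  inputs <- as.matrix(inputs)
  if (is.null(months)) months <- parse_month_colnames(inputs)
  if (nrow(inputs) != ens$input_dim) {
    stop(sprintf("input rows (%d) do not match the trained input dimension K = %d",
                 nrow(inputs), ens$input_dim), call. = FALSE)
  }
  m <- length(ens$seeds)
  pred <- matrix(NA_real_, ncol(inputs), m)
  for (i in seq_len(m)) {
    cfg <- ens$config
    cfg$seed <- ens$seeds[i]
    net <- init_esn(cfg, ens$input_dim)
    net$W_out <- ens$readouts[[i]]
    pred[, i] <- as.vector(predict(net, inputs))
  }
  ensemble_prediction(pred, months)
}

#' Restrict a temperature series to a month span
#'
#' @param x a [temperature_field_series()].
#' @param from,to `c(year, month)` inclusive bounds.
#' @return the restricted series.
#' @export
window_temps <- function(x, from, to) {
  stopifnot(inherits(x, "temp_field_series"))
  idx <- month_index(x$months$year, x$months$month)
  keep <- idx >= month_index(from[1], from[2]) & idx <= month_index(to[1], to[2])
  if (sum(keep) != month_index(to[1], to[2]) - month_index(from[1], from[2]) + 1L) {
    stop("series does not cover the requested span", call. = FALSE)
  }
  temperature_field_series(x$months[keep, , drop = FALSE], x$lat, x$lon,
                           x$values[keep, , , drop = FALSE],
                           scenario = x$scenario, normalized = x$normalized)
}
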