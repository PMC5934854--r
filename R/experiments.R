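# Configuration-driven experiment runner.

#' Default run configuration
#'
#' Nested list of all simulation defaults: a 1-s, 60 deg/s raised-cosine
#' leftward head turn starting at 0.5 s on a 2-s grid with dt = 0.01 s;
#' healthy sensor noise 10 deg/s and BVP neuronal noise 2 deg/s; an internal
#' model with decay 0.995, dynamic-prior innovation sd 6 deg/s, knowledge
#' weight 0.8 and assumed sensor noise 10 deg/s; interventions of sensor
#' inflation x10 and prior sharpening x3 with trained knowledge weight 0.95;
#' 5000 particles with resampling below half the particle count; 20
#' replicates.
#'
#' @return A nested configuration list (blocks `time`, `trajectory`,
#'   `world`, `knowledge`, `internal_model`, `interventions`, `inference`,
#'   `run`).
#' @export
default_config <- function() {
  list(
    time = list(dt = 0.01, total_time = 2.0),
    trajectory = list(amplitude = 60, movement_duration = 1.0, onset = 0.5,
                      shape = "raised_cosine_bell"),
    world = list(sensor_noise_sd = 10, bvp_noise_sd = 2),
    knowledge = list(gain = 1.0, noise_sd = 2.0, delay = 0.0),
    internal_model = list(decay = 0.995, process_noise_sd = 6,
                          knowledge_weight = 0.8,
                          assumed_sensor_noise_sd = 10,
                          initial_mean = 0, initial_sd = 1),
    interventions = list(sensor_inflation = 10, prior_sharpening = 3,
                         knowledge_weight_trained = 0.95),
    inference = list(n_particles = 5000, resample_threshold = 0.5),
    run = list(n_seeds = 20, master_seed = 1, output_dir = NULL,
               max_lag = 0.3, schema_version = 1)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a run configuration file
#'
#' Reads a YAML (or JSON) configuration and merges it over
#' [default_config()], so a file needs to state only the values it changes.
#'
#' @param path Path to a YAML or JSON file.
#' @return A configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  merge_config(default_config(), yaml::read_yaml(path))
}

config_truth <- function(config) {
  grid <- time_grid(config$time$dt, config$time$total_time)
  prof <- trajectory_profile(config$trajectory$amplitude,
                             config$trajectory$movement_duration,
                             config$trajectory$onset,
                             config$trajectory$shape)
  generate_trajectory(prof, grid)
}

movement_window <- function(config) {
  c(config$trajectory$onset,
    config$trajectory$onset + config$trajectory$movement_duration)
}

#' Run one experimental condition
#'
#' Composes the full pipeline for one condition and seed: generate the true
#' trajectory, the world's sensor observations and the knowledge signal,
#' run the particle filter under the agent's (possibly intervention-
#' modified) internal model, and compute the perception metrics.
#' Deterministic per `(spec, seed)`: observation, knowledge and filter
#' streams are independent sub-streams derived from `seed` via
#' [derive_seed()].
#'
#' @param spec A [condition_spec()] or condition label string.
#' @param config Configuration list, see [default_config()].
#' @param seed Integer seed for this run.
#' @param model Optional [internal_model()] overriding the one implied by
#'   `spec` (used by parameter sweeps).
#' @return List with elements `trace` (`posterior_trace`), `metrics`
#'   (one-row `data.frame` with `condition_label` and `seed` prepended),
#'   `truth` and `observations`.
#' @export
run_condition <- function(spec, config = default_config(), seed = 1,
                          model = NULL) {
  if (is.character(spec)) spec <- parse_condition_label(spec)
  truth <- config_truth(config)
  cond <- make_condition(spec, config)
  if (!is.null(model)) cond$model <- model
  obs <- generate_observations(truth, cond$world,
                               derive_seed(seed, "observations"))
  know <- generate_knowledge(truth, cond$knowledge, cond$switch_active,
                             derive_seed(seed, "knowledge"))
  trace <- particle_filter(obs, know, cond$switch_active, cond$model,
                           n_particles = config$inference$n_particles,
                           seed = derive_seed(seed, "filter"),
                           resample_threshold = config$inference$resample_threshold)
  met <- metrics_report(trace, truth, max_lag = config$run$max_lag,
                        window = movement_window(config))
  met <- cbind(data.frame(schema_version = config$run$schema_version,
                          condition_label = spec$label, seed = seed),
               met)
  list(trace = trace, metrics = met, truth = truth, observations = obs)
}

# Replicate seed: derived from the patient (not the full label) so that all
# conditions sharing a world — e.g. the three BVP rehabilitation arms — see
# identical observation and knowledge noise and comparisons are fully paired.
replicate_seed <- function(master_seed, spec, rep) {
  derive_seed(master_seed, spec$patient, rep)
}

run_conditions <- function(labels, config, models = NULL) {
  n_seeds <- config$run$n_seeds
  rows <- vector("list", length(labels) * n_seeds)
  mean_traces <- list()
  i <- 0
  for (j in seq_along(labels)) {
    spec <- parse_condition_label(labels[[j]])
    acc <- NULL
    for (rep in seq_len(n_seeds)) {
      res <- run_condition(spec, config,
                           seed = replicate_seed(config$run$master_seed,
                                                 spec, rep),
                           model = models[[j]])
      i <- i + 1
      rows[[i]] <- res$metrics
      acc <- if (is.null(acc)) res$trace$mean else acc + res$trace$mean
    }
    mean_traces[[spec$label]] <- acc / n_seeds
  }
  list(metrics = do.call(rbind, rows), mean_traces = mean_traces)
}

suite_summary <- function(metrics) {
  labs <- unique(metrics$condition_label)
  do.call(rbind, lapply(labs, function(l) {
    m <- metrics[metrics$condition_label == l, ]
    data.frame(condition_label = l,
               displacement_gain = mean(m$displacement_gain),
               peak_gain = mean(m$peak_gain),
               lag_s = mean(m$lag_s),
               mean_uncertainty = mean(m$mean_uncertainty),
               zero_motion_score_median = median(m$zero_motion_score),
               direction_correct_frac = mean(m$direction_correct))
  }))
}

new_suite_result <- function(suite, metrics, checks, mean_traces, config) {
  structure(list(suite = suite, metrics = metrics,
                 summary = suite_summary(metrics), checks = checks,
                 mean_traces = mean_traces, config = config),
            class = "vestib_suite")
}

#' @export
print.vestib_suite <- function(x, ...) {
  cat(sprintf("<vestib_suite> %s: %d conditions x %d replicates\n",
              x$suite, nrow(x$summary), x$config$run$n_seeds))
  print(x$summary, row.names = FALSE, digits = 3)
  cat("checks:\n")
  for (i in seq_len(nrow(x$checks)))
    cat(sprintf("  [%s] %s\n", if (x$checks$pass[i]) "PASS" else "FAIL",
                x$checks$property[i]))
  invisible(x)
}

write_suite_outputs <- function(result, out_dir) {
  if (is.null(out_dir)) return(invisible(result))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result$metrics,
            file.path(out_dir, paste0(result$suite, "_metrics.csv")),
            row.names = FALSE)
  tt <- config_truth(result$config)$grid$times
  for (l in names(result$mean_traces)) {
    write.csv(data.frame(time_s = tt, post_mean = result$mean_traces[[l]]),
              file.path(out_dir, paste0(result$suite, "_", l,
                                        "_mean_trace.csv")),
              row.names = FALSE)
  }
  jsonlite::write_json(
    list(suite = result$suite,
         checks = setNames(as.list(result$checks$pass),
                           result$checks$property),
         summary = result$summary),
    file.path(out_dir, paste0(result$suite, "_summary.json")),
    auto_unbox = TRUE, digits = NA)
  invisible(result)
}

#' Healthy vs. BVP perception suite
#'
#' Runs the four core conditions (healthy/BVP crossed with passive/active
#' movement) over `n_seeds` paired replicates and checks the qualitative
#' signatures: a healthy agent tracks the movement (displacement gain near
#' 1) with a lag that shrinks when the movement is self-initiated; an
#' untreated BVP agent's estimate stays near zero during passive movement,
#' and recovers the correct direction with attenuated amplitude during
#' active movement.
#'
#' @param config Configuration list, see [default_config()].
#' @return A `vestib_suite` object: per-run metrics, per-condition seed
#'   means, named property checks, and per-condition mean traces. Written as
#'   CSV/JSON under `config$run$output_dir` when that is set.
#' @export
run_perception_suite <- function(config = default_config()) {
  labels <- c("healthy_passive", "healthy_active", "bvp_passive",
              "bvp_active")
  res <- run_conditions(labels, config)
  s <- res$metrics
  agg <- function(l, col, f = mean) f(s[s$condition_label == l, col])
  checks <- data.frame(
    property = c("healthy_passive_tracks", "active_lag_reduced",
                 "bvp_passive_stays_zero", "bvp_active_attenuated"),
    pass = c(
      agg("healthy_passive", "displacement_gain") >= 0.8 &&
        agg("healthy_passive", "displacement_gain") <= 1.1,
      agg("healthy_active", "lag_s") < agg("healthy_passive", "lag_s"),
      agg("bvp_passive", "zero_motion_score", median) < 0.1,
      agg("bvp_active", "displacement_gain") > 0 &&
        agg("bvp_active", "displacement_gain") < 1 &&
        agg("bvp_active", "direction_correct") >= 0.9
    ))
  out <- new_suite_result("perception", s, checks, res$mean_traces, config)
  write_suite_outputs(out, config$run$output_dir)
}

#' Rehabilitation suite
#'
#' Runs the three BVP active-movement arms — untreated, conventional
#' rehabilitation (assumed sensor noise inflated), and conventional plus
#' cognitive training (dynamic prior sharpened, knowledge weight raised) —
#' on fully paired noise realizations, and checks that perceived
#' displacement gain increases strictly across the arms and that cognitive
#' training lowers the posterior uncertainty relative to conventional
#' rehabilitation alone.
#'
#' @inheritParams run_perception_suite
#' @return A `vestib_suite` object (see [run_perception_suite()]).
#' @export
run_rehab_suite <- function(config = default_config()) {
  labels <- c("bvp_active", "bvp_active_conventional",
              "bvp_active_conventional_plus_cognitive")
  res <- run_conditions(labels, config)
  s <- res$metrics
  g <- vapply(labels, function(l)
    mean(s$displacement_gain[s$condition_label == l]), numeric(1))
  u <- vapply(labels, function(l)
    mean(s$mean_uncertainty[s$condition_label == l]), numeric(1))
  checks <- data.frame(
    property = c("gain_strictly_ordered", "cognitive_reduces_uncertainty"),
    pass = c(g[1] < g[2] && g[2] < g[3], u[3] < u[2]))
  out <- new_suite_result("rehab", s, checks, res$mean_traces, config)
  write_suite_outputs(out, config$run$output_dir)
}

# Parameter sweeps -------------------------------------------------------------

#' Specify a parameter sweep
#'
#' @param parameter One of `"sensor_inflation"`, `"prior_sharpening"`,
#'   `"knowledge_weight"`.
#' @param values Strictly increasing numeric vector of at least 3 values.
#' @param base_condition Condition label or [condition_spec()] the sweep is
#'   applied to.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(parameter = c("sensor_inflation", "prior_sharpening",
                                     "knowledge_weight"),
                       values, base_condition = "bvp_active") {
  parameter <- match.arg(parameter)
  if (length(values) < 3 || any(diff(values) <= 0))
    stop("`values` must be >= 3 strictly increasing values", call. = FALSE)
  if (is.character(base_condition))
    base_condition <- parse_condition_label(base_condition)
  structure(list(parameter = parameter, values = values,
                 base_condition = base_condition),
            class = "sweep_spec")
}

sweep_model <- function(base_model, parameter, value) {
  switch(parameter,
    sensor_inflation = apply_conventional_rehab(base_model, value),
    prior_sharpening = apply_cognitive_training(base_model, value),
    knowledge_weight = {
      m <- base_model
      m$knowledge_weight <- value
      stopifnot(value >= 0, value <= 1)
      m
    })
}

#' Run a parameter sweep
#'
#' Dose-response exploration of an intervention mechanism: for every value
#' in the sweep, the base condition's internal model is modified
#' accordingly and run over `n_seeds` paired replicates. The monotonicity
#' summary reports the Spearman correlation of the per-value seed-mean
#' displacement gain with the swept values.
#'
#' @param sweep A [sweep_spec()].
#' @param config Configuration list.
#' @return List with `metrics` (one row per value and seed, columns
#'   `parameter` and `value` prepended), `by_value` (seed means per value),
#'   and `monotonicity` (Spearman correlation of seed-mean gain with value).
#' @export
run_sweep <- function(sweep, config = default_config()) {
  stopifnot(inherits(sweep, "sweep_spec"))
  spec <- sweep$base_condition
  base_model <- make_condition(spec, config)$model
  n_seeds <- config$run$n_seeds
  rows <- list()
  for (v in sweep$values) {
    model <- sweep_model(base_model, sweep$parameter, v)
    for (rep in seq_len(n_seeds)) {
      res <- run_condition(spec, config,
                           seed = replicate_seed(config$run$master_seed,
                                                 spec, rep),
                           model = model)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(parameter = sweep$parameter, value = v),
              res$metrics)
    }
  }
  metrics <- do.call(rbind, rows)
  by_value <- do.call(rbind, lapply(sweep$values, function(v) {
    m <- metrics[metrics$value == v, ]
    data.frame(value = v, displacement_gain = mean(m$displacement_gain),
               mean_uncertainty = mean(m$mean_uncertainty))
  }))
  mono <- suppressWarnings(
    cor(by_value$value, by_value$displacement_gain, method = "spearman"))
  out <- list(metrics = metrics, by_value = by_value, monotonicity = mono)
  if (!is.null(config$run$output_dir)) {
    dir.create(config$run$output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(metrics,
              file.path(config$run$output_dir,
                        paste0("sweep_", sweep$parameter, "_metrics.csv")),
              row.names = FALSE)
  }
  out
}

# Serialization helpers --------------------------------------------------------

#' Write a velocity or knowledge series to CSV
#'
#' Columns `time_s`, `value_deg_per_s`.
#'
#' @param series A `velocity_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  write.csv(data.frame(time_s = series$grid$times,
                       value_deg_per_s = series$values),
            path, row.names = FALSE)
  invisible(path)
}

#' Write a posterior trace to CSV
#'
#' Columns `time_s`, `post_mean`, `post_sd`, `ess`, `resampled`.
#'
#' @param trace A `posterior_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
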