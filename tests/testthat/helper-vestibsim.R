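# Shared fixture builders: everything is generated in code at test time.

default_grid <- function(dt = 0.01, total = 2) time_grid(dt, total)

default_truth <- function(grid = default_grid(), amplitude = 60) {
  generate_trajectory(
    trajectory_profile(amplitude = amplitude, movement_duration = 1,
                       onset = 0.5),
    grid)
}

# A trace wrapping an arbitrary mean series, for metric unit tests.
fake_trace <- function(mean, grid = default_grid(), sd = rep(1, length(mean))) {
  vestibsim:::new_posterior_trace(grid, mean, sd,
                                  ess = rep(NA_real_, length(mean)),
                                  resampled = rep(NA, length(mean)),
                                  method = "exact")
}

# Small-but-valid config for fast end-to-end runs.
quick_config <- function(n_particles = 1000, n_seeds = 3, master_seed = 42) {
  cfg <- default_config()
  cfg$inference$n_particles <- n_particles
  cfg$run$n_seeds <- n_seeds
  cfg$run$master_seed <- master_seed
  cfg
}

run_named_condition <- function(label, model, n_particles = 20000, seed = 7,
                                config = default_config()) {
  spec <- vestibsim:::parse_condition_label(label)
  truth <- default_truth()
  cond <- make_condition(spec, config)
  if (!missing(model) && !is.null(model)) cond$model <- model
  obs <- generate_observations(truth, cond$world, derive_seed(seed, "obs"))
  know <- generate_knowledge(truth, cond$knowledge, cond$switch_active,
                             derive_seed(seed, "know"))
  list(truth = truth, obs = obs, know = know, cond = cond,
       pf = particle_filter(obs, know, cond$switch_active, cond$model,
                            n_particles = n_particles,
                            seed = derive_seed(seed, "filter")),
       exact = exact_filter(obs, know, cond$switch_active, cond$model))
}
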