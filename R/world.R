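# Seeding utilities ---------------------------------------------------------

#' Derive a reproducible sub-stream seed
#'
#' Deterministic, platform-independent hash of a master seed plus any number
#' of string/number labels, reduced modulo 2^31 - 1. Used to give every
#' condition, replicate and random source (observations, knowledge, filter)
#' its own independent stream from one master seed, so conditions stay
#' matched across replicates for paired comparisons.
#'
#' The hash is a plain base-31 polynomial over the UTF-8 bytes of
#' `paste(master_seed, ..., sep = "/")`, accumulated modulo 2^31 - 1 in
#' double precision (all intermediates stay below 2^53, so the result is
#' exact on every platform).
#'
#' @param master_seed Integer master seed.
#' @param ... Labels (strings or numbers) identifying the sub-stream.
#' @return A single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(1, "healthy_passive", 3)
#' @export
derive_seed <- function(master_seed, ...) {
  key <- paste(c(format(master_seed, scientific = FALSE),
                 vapply(list(...), function(x) format(x, scientific = FALSE),
                        character(1))),
               collapse = "/")
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% m
  as.integer(h %% (m - 1L) + 1)
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# World (observation-generating) model ---------------------------------------

#' World model: how sensor observations arise
#'
#' In a healthy agent the semicircular canals report the true angular
#' velocity plus zero-mean Gaussian measurement noise. In bilateral
#' vestibulopathy (BVP) the end organs are deafferented: the afferent signal
#' is pure zero-mean neuronal noise, statistically independent of the true
#' head velocity. The BVP noise amplitude defaults to well below the healthy
#' measurement noise, reflecting the severely reduced spontaneous
#' variability of the deafferented nerve.
#'
#' @param sensor_mode `"healthy"` or `"bvp"`.
#' @param sensor_noise_sd Healthy measurement noise sd, deg/s.
#' @param bvp_noise_sd Neuronal noise sd of the deafferented signal, deg/s.
#' @return An object of class `world_model`.
#' @export
world_model <- function(sensor_mode = c("healthy", "bvp"),
                        sensor_noise_sd = 10, bvp_noise_sd = 2) {
  sensor_mode <- match.arg(sensor_mode)
  if (sensor_noise_sd < 0 || bvp_noise_sd < 0)
    stop("noise standard deviations must be >= 0", call. = FALSE)
  structure(list(sensor_mode = sensor_mode,
                 sensor_noise_sd = sensor_noise_sd,
                 bvp_noise_sd = bvp_noise_sd),
            class = "world_model")
}

#' Generate sensor observations
#'
#' Healthy mode: `y_t = truth_t + v_t`, `v_t ~ N(0, sensor_noise_sd^2)`.
#' BVP mode: `y_t = n_t ~ N(0, bvp_noise_sd^2)`, drawn independently of the
#' truth. Bit-reproducible given the seed; the caller's RNG state is left
#' untouched.
#'
#' @param truth A `velocity_series` of true head velocity.
#' @param world A [world_model()].
#' @param seed Integer seed for this observation stream.
#' @return A `velocity_series` of observations on the same grid.
#' @export
generate_observations <- function(truth, world, seed) {
  stopifnot(inherits(truth, "velocity_series"), inherits(world, "world_model"))
  n <- truth$grid$n_steps
  y <- with_seed(seed, {
    if (world$sensor_mode == "healthy")
      truth$values + rnorm(n, 0, world$sensor_noise_sd)
    else
      rnorm(n, 0, world$bvp_noise_sd)
  })
  new_velocity_series(truth$grid, y)
}

# Knowledge (efference-copy-like) signal --------------------------------------

#' Parameters of the knowledge signal
#'
#' The knowledge signal is the agent's expected head velocity, derived from
#' motor commands (efference copy) or higher-level sources. It is modelled on
#' the velocity level as a scaled, optionally delayed copy of the true
#' velocity plus Gaussian noise.
#'
#' @param knowledge_gain Dimensionless scale on the true velocity, in
#'   `[0, 1.5]`.
#' @param knowledge_noise_sd Noise sd, deg/s.
#' @param knowledge_delay Delay in seconds (>= 0); the truth is taken as 0
#'   before time 0.
#' @return An object of class `knowledge_params`.
#' @export
knowledge_params <- function(knowledge_gain = 1, knowledge_noise_sd = 2,
                             knowledge_delay = 0) {
  if (knowledge_gain < 0 || knowledge_gain > 1.5)
    stop("`knowledge_gain` must lie in [0, 1.5]", call. = FALSE)
  if (knowledge_noise_sd < 0) stop("`knowledge_noise_sd` must be >= 0",
                                   call. = FALSE)
  if (knowledge_delay < 0) stop("`knowledge_delay` must be >= 0",
                                call. = FALSE)
  structure(list(knowledge_gain = knowledge_gain,
                 knowledge_noise_sd = knowledge_noise_sd,
                 knowledge_delay = knowledge_delay),
            class = "knowledge_params")
}

#' Generate the knowledge signal
#'
#' When the movement is passive (`switch_active = FALSE`) no knowledge is
#' available and the signal is identically zero. When active,
#' `u_t = gain * truth(t - delay) + e_t` with `e_t ~ N(0, noise_sd^2)`.
#'
#' @param truth A `velocity_series` of true head velocity.
#' @param params A [knowledge_params()].
#' @param switch_active Logical: is the movement self-initiated?
#' @param seed Integer seed for the knowledge noise stream.
#' @return A `knowledge_signal` (a `velocity_series` subclass) on the same
#'   grid.
#' @export
generate_knowledge <- function(truth, params, switch_active, seed) {
  stopifnot(inherits(truth, "velocity_series"),
            inherits(params, "knowledge_params"))
  grid <- truth$grid
  if (!isTRUE(switch_active)) {
    return(new_velocity_series(grid, numeric(grid$n_steps),
                               class = c("knowledge_signal",
                                         "velocity_series")))
  }
  shift <- as.integer(round(params$knowledge_delay / grid$dt))
  base <- if (shift > 0)
    c(numeric(min(shift, grid$n_steps)),
      head(truth$values, max(0L, grid$n_steps - shift)))
  else truth$values
  u <- with_seed(seed,
                 params$knowledge_gain * base +
                   rnorm(grid$n_steps, 0, params$knowledge_noise_sd))
  new_velocity_series(grid, u,
                      class = c("knowledge_signal", "velocity_series"))
}
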