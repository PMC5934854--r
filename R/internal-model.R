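# The agent's assumed generative model: the object interventions act on.

#' Internal model assumed by the agent
#'
#' The process model (the agent's "laws of physics" for head velocity) is a
#' damped random walk with an optional pull toward the knowledge signal:
#' the one-step prediction mean is
#' `(1 - b) * decay * v_prev + b * u_t` when the active switch is on
#' (`b = knowledge_weight`), and `decay * v_prev` when off, with Gaussian
#' innovation sd `process_noise_sd` — the width of the dynamic prior. The
#' sensor model assumes Gaussian measurement noise of sd
#' `assumed_sensor_noise_sd`; this assumed width is a belief and need not
#' match the world's true noise (an untreated BVP agent keeps the healthy
#' value — it does not know its sensors are broken).
#'
#' @param decay Per-step velocity persistence in `[0, 1]`.
#' @param process_noise_sd Innovation sd of the dynamic prior, deg/s per step.
#' @param knowledge_weight Pull toward the knowledge signal, `b` in `[0, 1]`.
#' @param assumed_sensor_noise_sd Sensor noise sd assumed by the filter, deg/s.
#' @param initial_mean,initial_sd Gaussian prior on the initial velocity,
#'   deg/s.
#' @return An object of class `internal_model`.
#' @examples
#' m <- internal_model()
#' predict_step(10, 30, switch_active = TRUE, model = m)
#' @export
internal_model <- function(decay = 0.995, process_noise_sd = 6,
                           knowledge_weight = 0.8,
                           assumed_sensor_noise_sd = 10,
                           initial_mean = 0, initial_sd = 1) {
  if (decay < 0 || decay > 1)
    stop("`decay` must lie in [0, 1]", call. = FALSE)
  if (knowledge_weight < 0 || knowledge_weight > 1)
    stop("`knowledge_weight` must lie in [0, 1]", call. = FALSE)
  sds <- c(process_noise_sd, assumed_sensor_noise_sd, initial_sd)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("standard deviations must be finite and >= 0", call. = FALSE)
  structure(list(decay = decay, process_noise_sd = process_noise_sd,
                 knowledge_weight = knowledge_weight,
                 assumed_sensor_noise_sd = assumed_sensor_noise_sd,
                 initial_mean = initial_mean, initial_sd = initial_sd),
            class = "internal_model")
}

#' @export
print.internal_model <- function(x, ...) {
  cat("<internal_model>\n")
  cat(sprintf("  process : decay %g, innovation sd %g deg/s (dynamic prior width)\n",
              x$decay, x$process_noise_sd))
  cat(sprintf("  knowledge weight b = %g\n", x$knowledge_weight))
  cat(sprintf("  sensor  : assumed noise sd %g deg/s\n",
              x$assumed_sensor_noise_sd))
  cat(sprintf("  initial : N(%g, %g^2)\n", x$initial_mean, x$initial_sd))
  invisible(x)
}

#' One-step prediction (the dynamic prior)
#'
#' Deterministic mapping from the previous velocity and the knowledge value
#' to the mean and sd of the one-step-ahead predictive distribution.
#' Vectorized over `prev_velocity`.
#'
#' @param prev_velocity Previous velocity estimate(s), deg/s.
#' @param knowledge_value Knowledge signal value at the current step, deg/s.
#' @param switch_active Logical: use the knowledge signal?
#' @param model An [internal_model()].
#' @return List with elements `mean` (same length as `prev_velocity`) and
#'   `sd` (scalar, `process_noise_sd`).
#' @export
predict_step <- function(prev_velocity, knowledge_value, switch_active, model) {
  base <- model$decay * prev_velocity
  m <- if (isTRUE(switch_active))
    (1 - model$knowledge_weight) * base +
      model$knowledge_weight * knowledge_value
  else base
  list(mean = m, sd = model$process_noise_sd)
}

#' Observation log-likelihood
#'
#' Gaussian log-density of an observation given a velocity, under the
#' agent's assumed sensor noise. Vectorized over `velocity`.
#'
#' @param observation Observed value, deg/s.
#' @param velocity Hypothesized velocity (or vector of particle values).
#' @param model An [internal_model()]; `assumed_sensor_noise_sd` must be
#'   positive (use [exact_filter()] for the noiseless limit).
#' @return Log-density value(s).
#' @export
observation_loglik <- function(observation, velocity, model) {
  if (model$assumed_sensor_noise_sd <= 0)
    stop("assumed sensor noise sd must be > 0 for the likelihood; ",
         "use exact_filter() for the noiseless limit", call. = FALSE)
  dnorm(observation, mean = velocity, sd = model$assumed_sensor_noise_sd,
        log = TRUE)
}

# Interventions ---------------------------------------------------------------

#' Conventional rehabilitation: down-weight the vestibular data
#'
#' Conventional rehabilitation teaches the patient to rely less on the
#' (uninformative) vestibular signal, modelled as inflating the width of the
#' assumed sensor noise distribution. Physiology is untouched: only the
#' belief changes.
#'
#' @param model An [internal_model()].
#' @param inflation Multiplicative factor >= 1 on `assumed_sensor_noise_sd`.
#' @return A modified copy of `model`.
#' @export
apply_conventional_rehab <- function(model, inflation) {
  stopifnot(inherits(model, "internal_model"))
  if (!is.finite(inflation) || inflation < 1)
    stop("`inflation` must be >= 1", call. = FALSE)
  model$assumed_sensor_noise_sd <- model$assumed_sensor_noise_sd * inflation
  model
}

#' Cognitive training: sharpen the dynamic prior
#'
#' Cognitive training (e.g. mental body-rotation practice) improves the use
#' of, and the confidence in, predicted head motion: the dynamic prior's
#' innovation sd is divided by `prior_sharpening` and the knowledge weight is
#' raised to `knowledge_weight_new`.
#'
#' @param model An [internal_model()].
#' @param prior_sharpening Factor >= 1 dividing `process_noise_sd`.
#' @param knowledge_weight_new New knowledge weight; must not be lower than
#'   the model's current weight (training cannot un-learn reliance on
#'   predictions).
#' @return A modified copy of `model`.
#' @export
apply_cognitive_training <- function(model, prior_sharpening,
                                     knowledge_weight_new = model$knowledge_weight) {
  stopifnot(inherits(model, "internal_model"))
  if (!is.finite(prior_sharpening) || prior_sharpening < 1)
    stop("`prior_sharpening` must be >= 1", call. = FALSE)
  if (knowledge_weight_new < model$knowledge_weight ||
      knowledge_weight_new > 1)
    stop("`knowledge_weight_new` must lie in [current weight, 1]",
         call. = FALSE)
  model$process_noise_sd <- model$process_noise_sd / prior_sharpening
  model$knowledge_weight <- knowledge_weight_new
  model
}

# Conditions -------------------------------------------------------------------

#' Named experimental condition
#'
#' @param patient `"healthy"` or `"bvp"`.
#' @param movement `"passive"` or `"active"`.
#' @param intervention `"none"`, `"conventional"` or
#'   `"conventional_plus_cognitive"`; interventions model rehabilitation of
#'   BVP patients and are only valid with `patient = "bvp"`.
#' @param label Optional label; defaults to the parts joined by `_`.
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(patient = c("healthy", "bvp"),
                           movement = c("passive", "active"),
                           intervention = c("none", "conventional",
                                            "conventional_plus_cognitive"),
                           label = NULL) {
  patient <- match.arg(patient)
  movement <- match.arg(movement)
  intervention <- match.arg(intervention)
  if (intervention != "none" && patient != "bvp")
    stop("interventions model rehabilitation of BVP patients; ",
         "use patient = \"bvp\"", call. = FALSE)
  if (is.null(label)) {
    label <- paste(patient, movement, sep = "_")
    if (intervention != "none") label <- paste(label, intervention, sep = "_")
  }
  structure(list(patient = patient, movement = movement,
                 intervention = intervention, label = label),
            class = "condition_spec")
}

# Parse labels like "bvp_active_conventional_plus_cognitive".
parse_condition_label <- function(label) {
  parts <- strsplit(label, "_", fixed = TRUE)[[1]]
  if (length(parts) < 2)
    stop("unresolvable condition label: ", label, call. = FALSE)
  intervention <- if (length(parts) == 2) "none"
    else paste(parts[-(1:2)], collapse = "_")
  condition_spec(parts[1], parts[2], intervention, label = label)
}

#' Instantiate a condition
#'
#' Maps a [condition_spec()] plus a configuration to the objects a run
#' needs: the world model, the agent's internal model (with any
#' interventions applied), the active/passive switch, and the knowledge
#' parameters. An untreated BVP agent keeps the healthy internal model —
#' the mis-specified sensor belief is what lets the noise-only data pull the
#' posterior toward zero.
#'
#' @param spec A [condition_spec()] or a condition label string.
#' @param config Configuration list, see [default_config()].
#' @return List with elements `world`, `model`, `switch_active`, `knowledge`.
#' @export
make_condition <- function(spec, config = default_config()) {
  if (is.character(spec)) spec <- parse_condition_label(spec)
  stopifnot(inherits(spec, "condition_spec"))
  world <- world_model(sensor_mode = spec$patient,
                       sensor_noise_sd = config$world$sensor_noise_sd,
                       bvp_noise_sd = config$world$bvp_noise_sd)
  im <- config$internal_model
  model <- internal_model(decay = im$decay,
                          process_noise_sd = im$process_noise_sd,
                          knowledge_weight = im$knowledge_weight,
                          assumed_sensor_noise_sd = im$assumed_sensor_noise_sd,
                          initial_mean = im$initial_mean,
                          initial_sd = im$initial_sd)
  if (spec$intervention %in% c("conventional", "conventional_plus_cognitive"))
    model <- apply_conventional_rehab(model,
                                      config$interventions$sensor_inflation)
  if (spec$intervention == "conventional_plus_cognitive")
    model <- apply_cognitive_training(model,
                                      config$interventions$prior_sharpening,
                                      config$interventions$knowledge_weight_trained)
  kp <- config$knowledge
  list(world = world, model = model,
       switch_active = spec$movement == "active",
       knowledge = knowledge_params(kp$gain, kp$noise_sd, kp$delay))
}
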