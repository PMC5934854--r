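# Sequential Bayesian inference of head velocity.

new_posterior_trace <- function(grid, mean, sd, ess, resampled, method) {
  stopifnot(length(mean) == grid$n_steps, length(sd) == grid$n_steps,
            all(sd >= 0))
  structure(list(grid = grid, mean = mean, sd = sd, ess = ess,
                 resampled = resampled, method = method),
            class = "posterior_trace")
}

#' @export
print.posterior_trace <- function(x, ...) {
  cat(sprintf("<posterior_trace> method = %s, %d steps, dt = %g s\n",
              x$method, x$grid$n_steps, x$grid$dt))
  cat(sprintf("  posterior mean range [%.3g, %.3g] deg/s, mean sd %.3g deg/s\n",
              min(x$mean), max(x$mean), mean(x$sd)))
  if (!all(is.na(x$resampled)))
    cat(sprintf("  resampled at %d of %d steps\n",
                sum(x$resampled), x$grid$n_steps))
  invisible(x)
}

#' @export
as.data.frame.posterior_trace <- function(x, ...) {
  data.frame(time_s = x$grid$times, post_mean = x$mean, post_sd = x$sd,
             ess = if (is.null(x$ess)) NA_real_ else x$ess,
             resampled = x$resampled)
}

#' @export
plot.posterior_trace <- function(x, truth = NULL, observations = NULL, ...,
                                 main = NULL) {
  tt <- x$grid$times
  ylim <- range(x$mean - x$sd, x$mean + x$sd,
                if (!is.null(truth)) truth$values,
                if (!is.null(observations)) observations$values)
  plot(tt, x$mean, type = "n", xlab = "time (s)",
       ylab = "angular velocity (deg/s)", ylim = ylim, main = main, ...)
  polygon(c(tt, rev(tt)), c(x$mean - x$sd, rev(x$mean + x$sd)),
          border = NA, col = adjustcolor("grey", 0.5))
  if (!is.null(observations))
    points(tt, observations$values, pch = 16, cex = 0.4,
           col = adjustcolor("steelblue", 0.6))
  if (!is.null(truth)) lines(tt, truth$values, col = "black", lwd = 2)
  lines(tt, x$mean, col = "deeppink3", lwd = 2)
  abline(h = 0, col = "grey70", lty = 3)
  invisible(x)
}

#' Systematic resampling
#'
#' One stratified sweep through the cumulative weights: offspring positions
#' are `(u + j) / N`, `j = 0, ..., N - 1`, for a single uniform draw `u`.
#' Every particle's offspring count differs from `N * w_i` by less than 1,
#' and the output weights are uniform.
#'
#' @param ensemble A `particle_ensemble`: list with `velocities` and
#'   normalized `weights`.
#' @param u A single number in `[0, 1)` (the stratification offset).
#' @param n_out Number of offspring to draw (defaults to the ensemble size).
#' @return A resampled `particle_ensemble` of `n_out` particles with uniform
#'   weights.
#' @export
systematic_resample <- function(ensemble, u, n_out = length(ensemble$weights)) {
  w <- ensemble$weights
  stopifnot(length(w) >= 2, n_out >= 2, u >= 0, u < 1,
            abs(sum(w) - 1) < 1e-9)
  cw <- cumsum(w)
  cw <- cw / cw[length(cw)] # guard against accumulated round-off
  idx <- findInterval((u + seq_len(n_out) - 1) / n_out, cw) + 1L
  structure(list(velocities = ensemble$velocities[idx],
                 weights = rep(1 / n_out, n_out)),
            class = "particle_ensemble")
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) stop("degenerate particle weights", call. = FALSE)
  m + log(sum(exp(x - m)))
}

#' Bootstrap particle filter
#'
#' Sequential Monte Carlo inference of head velocity. Particles are
#' initialized from the internal model's initial distribution; at every step
#' each particle is propagated through the one-step prediction
#' ([predict_step()]) plus a Gaussian innovation of sd `process_noise_sd`,
#' then re-weighted by the observation likelihood
#' ([observation_loglik()]). Weights are kept in log space and normalized by
#' log-sum-exp. When the effective sample size `1 / sum(w^2)` drops below
#' `resample_threshold * n_particles`, the ensemble is resampled
#' systematically. Reproducible given the seed.
#'
#' @param observations A `velocity_series` of sensor observations.
#' @param knowledge A `knowledge_signal` on the same grid.
#' @param switch_active Logical: use the knowledge signal in prediction?
#' @param model An [internal_model()].
#' @param n_particles Number of particles (>= 100).
#' @param seed Integer seed.
#' @param resample_threshold ESS fraction below which to resample.
#' @return A `posterior_trace` with per-step weighted posterior mean, sd
#'   (weighted, biased estimator), ESS and resampling flags.
#' @examples
#' g <- time_grid(0.01, 2)
#' truth <- generate_trajectory(trajectory_profile(), g)
#' obs <- generate_observations(truth, world_model("healthy"), seed = 1)
#' u <- generate_knowledge(truth, knowledge_params(), FALSE, seed = 2)
#' tr <- particle_filter(obs, u, FALSE, internal_model(),
#'                       n_particles = 500, seed = 3)
#' @export
particle_filter <- function(observations, knowledge, switch_active, model,
                            n_particles = 5000, seed = 1,
                            resample_threshold = 0.5) {
  stopifnot(inherits(observations, "velocity_series"),
            inherits(knowledge, "velocity_series"),
            inherits(model, "internal_model"))
  if (!same_grid(observations$grid, knowledge$grid))
    stop("observations and knowledge must share one time grid", call. = FALSE)
  if (n_particles < 100) stop("`n_particles` must be >= 100", call. = FALSE)
  grid <- observations$grid
  n <- grid$n_steps
  y <- observations$values
  u <- knowledge$values
  post_mean <- post_sd <- ess <- numeric(n)
  resampled <- logical(n)
  with_seed(seed, {
    v <- rnorm(n_particles, model$initial_mean, model$initial_sd)
    logw <- rep(0, n_particles)
    for (k in seq_len(n)) {
      pred <- predict_step(v, u[k], switch_active, model)
      v <- pred$mean + rnorm(n_particles, 0, pred$sd)
      logw <- logw + observation_loglik(y[k], v, model)
      lw <- logw - log_sum_exp(logw)
      w <- exp(lw)
      m <- sum(w * v)
      post_mean[k] <- m
      post_sd[k] <- sqrt(max(0, sum(w * (v - m)^2)))
      ess[k] <- 1 / sum(w^2)
      if (ess[k] < resample_threshold * n_particles) {
        ens <- systematic_resample(
          structure(list(velocities = v, weights = w),
                    class = "particle_ensemble"),
          runif(1))
        v <- ens$velocities
        logw <- rep(0, n_particles)
        resampled[k] <- TRUE
      }
    }
  })
  new_posterior_trace(grid, post_mean, post_sd, ess, resampled, "particle")
}

#' Exact conditionally linear-Gaussian filter
#'
#' Closed-form Kalman-style recursion for the same model the particle filter
#' targets: with the knowledge signal treated as a known input, prediction
#' and update are both Gaussian, so the filter is exact and serves as the
#' correctness oracle for [particle_filter()]. Prediction mean comes from
#' [predict_step()]; prediction variance is
#' `(decay * (1 - b * switch))^2 * prev_var + process_noise_sd^2`. A zero
#' assumed sensor noise is allowed: the posterior then collapses onto the
#' observations.
#'
#' @inheritParams particle_filter
#' @return A `posterior_trace` (no ESS / resampling: `ess` is `NA`).
#' @export
exact_filter <- function(observations, knowledge, switch_active, model) {
  stopifnot(inherits(observations, "velocity_series"),
            inherits(model, "internal_model"))
  if (!same_grid(observations$grid, knowledge$grid))
    stop("observations and knowledge must share one time grid", call. = FALSE)
  grid <- observations$grid
  n <- grid$n_steps
  y <- observations$values
  u <- knowledge$values
  b <- if (isTRUE(switch_active)) model$knowledge_weight else 0
  coef_prev <- model$decay * (1 - b)
  sv2 <- model$assumed_sensor_noise_sd^2
  post_mean <- post_sd <- numeric(n)
  m <- model$initial_mean
  P <- model$initial_sd^2
  for (k in seq_len(n)) {
    m_pred <- predict_step(m, u[k], switch_active, model)$mean
    P_pred <- coef_prev^2 * P + model$process_noise_sd^2
    K <- if (sv2 == 0) 1 else P_pred / (P_pred + sv2)
    m <- m_pred + K * (y[k] - m_pred)
    P <- (1 - K) * P_pred
    post_mean[k] <- m
    post_sd[k] <- sqrt(max(0, P))
  }
  new_posterior_trace(grid, post_mean, post_sd, ess = rep(NA_real_, n),
                      resampled = rep(NA, n), method = "exact")
}

#' Off-line imagery mode
#'
#' Runs the prediction chain with no sensory update at any step — the model
#' imagining self-motion rather than inferring it from data. The mean follows
#' the [predict_step()] recursion driven by the knowledge signal (imagery
#' always uses knowledge); the variance follows the prediction-variance
#' recursion and is never reduced by data.
#'
#' @param knowledge A `knowledge_signal`.
#' @param model An [internal_model()].
#' @return A `posterior_trace` with `method = "imagery"`.
#' @export
run_imagery <- function(knowledge, model) {
  stopifnot(inherits(knowledge, "velocity_series"),
            inherits(model, "internal_model"))
  grid <- knowledge$grid
  n <- grid$n_steps
  u <- knowledge$values
  coef_prev <- model$decay * (1 - model$knowledge_weight)
  post_mean <- post_sd <- numeric(n)
  m <- model$initial_mean
  P <- model$initial_sd^2
  for (k in seq_len(n)) {
    m <- predict_step(m, u[k], TRUE, model)$mean
    P <- coef_prev^2 * P + model$process_noise_sd^2
    post_mean[k] <- m
    post_sd[k] <- sqrt(P)
  }
  new_posterior_trace(grid, post_mean, post_sd, ess = rep(NA_real_, n),
                      resampled = rep(NA, n), method = "imagery")
}

# Front-end estimator ---------------------------------------------------------

#' Infer head velocity from sensor observations
#'
#' The package's central estimator: sequential Bayesian inference of the
#' latent head velocity given sensor observations and (optionally) an
#' efference-copy-like knowledge signal. `method = "particle"` runs the
#' bootstrap particle filter; `method = "exact"` the closed-form
#' conditionally linear-Gaussian filter.
#'
#' @inheritParams particle_filter
#' @param method `"particle"` or `"exact"`.
#' @param truth Optional `velocity_series` of the true velocity; stored for
#'   [summary.vestib_filter()] and [plot.posterior_trace()].
#' @return An object of class `vestib_filter` (extending `posterior_trace`)
#'   with the inputs attached; supports `print`, `summary`, `plot`,
#'   `fitted`, `residuals` and `as.data.frame`.
#' @examples
#' g <- time_grid(0.01, 2)
#' truth <- generate_trajectory(trajectory_profile(), g)
#' obs <- generate_observations(truth, world_model("healthy"), seed = 1)
#' u <- generate_knowledge(truth, knowledge_params(), TRUE, seed = 2)
#' fit <- vestib_filter(obs, u, switch_active = TRUE, n_particles = 500,
#'                      seed = 3, truth = truth)
#' summary(fit)
#' @export
vestib_filter <- function(observations, knowledge, switch_active,
                          model = internal_model(),
                          method = c("particle", "exact"),
                          n_particles = 5000, seed = 1,
                          resample_threshold = 0.5, truth = NULL) {
  method <- match.arg(method)
  trace <- if (method == "particle")
    particle_filter(observations, knowledge, switch_active, model,
                    n_particles = n_particles, seed = seed,
                    resample_threshold = resample_threshold)
  else exact_filter(observations, knowledge, switch_active, model)
  trace$observations <- observations
  trace$knowledge <- knowledge
  trace$switch_active <- switch_active
  trace$model <- model
  trace$truth <- truth
  trace$call <- match.call()
  class(trace) <- c("vestib_filter", class(trace))
  trace
}

#' @export
fitted.vestib_filter <- function(object, ...) object$mean

#' @export
residuals.vestib_filter <- function(object, ...)
  object$observations$values - object$mean

#' @rdname vestib_filter
#' @param object A `vestib_filter` object.
#' @param ... Unused.
#' @export
summary.vestib_filter <- function(object, ...) {
  out <- list(method = object$method, n_steps = object$grid$n_steps,
              switch_active = object$switch_active,
              mean_sd = mean(object$sd),
              metrics = if (!is.null(object$truth))
                metrics_report(object, object$truth))
  class(out) <- "summary.vestib_filter"
  out
}

#' @export
print.summary.vestib_filter <- function(x, ...) {
  cat(sprintf("Head-velocity inference (%s filter), %d steps, %s movement\n",
              x$method, x$n_steps,
              if (isTRUE(x$switch_active)) "active" else "passive"))
  cat(sprintf("  mean posterior sd: %.3g deg/s\n", x$mean_sd))
  if (!is.null(x$metrics)) {
    m <- x$metrics
    cat(sprintf("  perceived gain: peak %.3f, displacement %.3f (%s direction)\n",
                m$peak_gain, m$displacement_gain,
                if (m$direction_correct) "correct" else "wrong"))
    cat(sprintf("  response lag: %.3f s; zero-motion score: %.3f\n",
                m$lag_s, m$zero_motion_score))
  }
  invisible(x)
}
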