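#' Discrete time grid
#'
#' Builds the evenly spaced time grid on which all series live. The grid
#' starts at 0 and contains `round(total_time / dt) + 1` points, so both
#' endpoints are included.
#'
#' @param dt Step size in seconds. Must be positive.
#' @param total_time Total simulated time in seconds. Must be at least `2 * dt`.
#'
#' @return An object of class `time_grid`: a list with elements `dt`,
#'   `n_steps` and `times`.
#' @examples
#' g <- time_grid(0.5, 1)
#' g$times
#' @export
time_grid <- function(dt, total_time) {
  stopifnot(is.numeric(dt), length(dt) == 1L, is.numeric(total_time),
            length(total_time) == 1L)
  if (!is.finite(dt) || dt <= 0)
    stop("`dt` must be a positive number", call. = FALSE)
  if (!is.finite(total_time) || total_time < 2 * dt)
    stop("`total_time` must be at least 2 * dt", call. = FALSE)
  n_steps <- as.integer(round(total_time / dt)) + 1L
  structure(
    list(dt = dt, n_steps = n_steps, times = (seq_len(n_steps) - 1) * dt),
    class = "time_grid"
  )
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> dt = %g s, %d steps, [0, %g] s\n",
              x$dt, x$n_steps, x$times[x$n_steps]))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$dt, b$dt)) && a$n_steps == b$n_steps
}

#' Head-turn velocity profile
#'
#' Describes the true head angular velocity during a single yaw head turn.
#' The default shape is a raised-cosine bell,
#' \eqn{\Omega(t) = A \sin^2(\pi (t - t_0)/T)} inside the movement window and
#' zero outside: smooth, zero at both endpoints, peaking at the window
#' midpoint. Positive amplitude means a leftward turn.
#'
#' @param amplitude Signed peak angular velocity in deg/s.
#' @param movement_duration Duration of the turn in seconds.
#' @param onset Movement onset in seconds.
#' @param shape One of `"raised_cosine_bell"`, `"trapezoid"`, `"zero"`.
#'
#' @return An object of class `trajectory_profile`.
#' @export
trajectory_profile <- function(amplitude = 60, movement_duration = 1,
                               onset = 0.5,
                               shape = c("raised_cosine_bell", "trapezoid",
                                         "zero")) {
  shape <- match.arg(shape)
  if (!is.finite(movement_duration) || movement_duration <= 0)
    stop("`movement_duration` must be positive", call. = FALSE)
  if (!is.finite(onset) || onset < 0)
    stop("`onset` must be non-negative", call. = FALSE)
  structure(
    list(amplitude = amplitude, movement_duration = movement_duration,
         onset = onset, shape = shape),
    class = "trajectory_profile"
  )
}

new_velocity_series <- function(grid, values, class = "velocity_series") {
  stopifnot(length(values) == grid$n_steps, all(is.finite(values)))
  structure(list(grid = grid, values = values), class = class)
}

#' @export
print.velocity_series <- function(x, ...) {
  cat(sprintf("<%s> %d steps, dt = %g s, range [%.3g, %.3g] deg/s\n",
              class(x)[1L], x$grid$n_steps, x$grid$dt,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Generate the true head-velocity trajectory
#'
#' Evaluates a [trajectory_profile()] on a [time_grid()]. Deterministic: the
#' same profile and grid always give the same series.
#'
#' @param profile A [trajectory_profile()].
#' @param grid A [time_grid()].
#'
#' @return A `velocity_series`: list with elements `grid` and `values`
#'   (deg/s, one per grid point).
#' @examples
#' truth <- generate_trajectory(trajectory_profile(), time_grid(0.01, 2))
#' max(truth$values) # peak velocity
#' @export
generate_trajectory <- function(profile, grid) {
  stopifnot(inherits(profile, "trajectory_profile"), inherits(grid, "time_grid"))
  t_end <- grid$times[grid$n_steps]
  if (profile$shape != "zero" &&
      profile$onset + profile$movement_duration > t_end + 1e-9)
    stop("movement window exceeds the time grid", call. = FALSE)
  tt <- grid$times
  rel <- (tt - profile$onset) / profile$movement_duration
  inside <- rel >= 0 & rel <= 1
  v <- numeric(grid$n_steps)
  if (profile$shape == "raised_cosine_bell") {
    v[inside] <- profile$amplitude * sin(pi * rel[inside])^2
  } else if (profile$shape == "trapezoid") {
    # linear ramps over the first/last fifth of the window, flat top between
    r <- rel[inside]
    v[inside] <- profile$amplitude * pmin(1, pmin(r, 1 - r) / 0.2)
  }
  new_velocity_series(grid, v)
}

#' Displacement carried by a velocity series
#'
#' Time-integral of the series by the rectangle rule (deg).
#'
#' @param series A `velocity_series`.
#' @return Total angular displacement in degrees.
#' @export
series_displacement <- function(series) {
  sum(series$values) * series$grid$dt
}
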