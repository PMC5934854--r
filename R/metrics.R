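# Perception metrics computed from a posterior trace.

#' Perceived gain of the velocity estimate
#'
#' Two operationalizations of "perceived amplitude relative to true
#' amplitude": `peak_gain` is the posterior mean at the time of the true
#' speed peak, divided by the signed true peak; `displacement_gain` is the
#' ratio of time-integrals (estimated over true displacement) and is the
#' more robust headline metric. A reduced displacement gain is the model's
#' analogue of a reduced vestibulo-ocular reflex gain.
#'
#' @param trace A `posterior_trace`.
#' @param truth A `velocity_series`, not identically zero.
#' @return List with `peak_gain` and `displacement_gain`.
#' @export
perceived_gain <- function(trace, truth) {
  stopifnot(inherits(trace, "posterior_trace"),
            inherits(truth, "velocity_series"),
            same_grid(trace$grid, truth$grid))
  if (all(truth$values == 0))
    stop("truth is identically zero; use zero_motion_score()", call. = FALSE)
  i_peak <- which.max(abs(truth$values))
  list(peak_gain = trace$mean[i_peak] / truth$values[i_peak],
       displacement_gain = sum(trace$mean) / sum(truth$values))
}

#' Response lag of the velocity estimate
#'
#' The non-negative lag (seconds) maximizing the cross-correlation between
#' the posterior mean and the delayed true velocity, searched on the
#' discrete grid over `[0, max_lag]` with parabolic interpolation around the
#' discrete argmax for sub-step resolution. A causal filter can only lag the
#' stimulus (apart from noise), hence the non-negative search range.
#'
#' @param trace A `posterior_trace`.
#' @param truth A non-constant `velocity_series`.
#' @param max_lag Largest lag searched, seconds (>= `dt`).
#' @return Lag in seconds. A flat (degenerate) trace returns 0 with a
#'   warning and attribute `degenerate = TRUE`.
#' @export
response_lag <- function(trace, truth, max_lag = 0.3) {
  stopifnot(inherits(trace, "posterior_trace"),
            inherits(truth, "velocity_series"),
            same_grid(trace$grid, truth$grid))
  dt <- trace$grid$dt
  if (max_lag < dt) stop("`max_lag` must be >= dt", call. = FALSE)
  if (sd(truth$values) == 0)
    stop("truth is constant; lag is undefined", call. = FALSE)
  if (sd(trace$mean) == 0) {
    warning("flat posterior mean: lag is degenerate, returning 0")
    return(structure(0, degenerate = TRUE))
  }
  n <- trace$grid$n_steps
  lags <- 0:min(n - 3L, as.integer(round(max_lag / dt)))
  cc <- vapply(lags, function(L) {
    x <- trace$mean[(1 + L):n]
    y <- truth$values[1:(n - L)]
    if (sd(x) == 0 || sd(y) == 0) -Inf else cor(x, y)
  }, numeric(1))
  i <- which.max(cc)
  lag <- lags[i]
  # parabolic refinement when the argmax is interior
  if (i > 1 && i < length(cc) && is.finite(cc[i - 1]) && is.finite(cc[i + 1])) {
    denom <- cc[i - 1] - 2 * cc[i] + cc[i + 1]
    if (denom < 0) lag <- lag + 0.5 * (cc[i - 1] - cc[i + 1]) / denom
  }
  min(max(lag * dt, 0), max_lag)
}

#' Mean posterior uncertainty over a time window
#'
#' Arithmetic mean of the posterior sd over `window` (default: the whole
#' trace). Conditions with a sharper dynamic prior or more informative data
#' produce smaller values.
#'
#' @param trace A `posterior_trace`.
#' @param window Numeric `c(start, end)` in seconds.
#' @return Mean posterior sd, deg/s.
#' @export
mean_uncertainty <- function(trace, window = NULL) {
  stopifnot(inherits(trace, "posterior_trace"))
  tt <- trace$grid$times
  keep <- if (is.null(window)) rep(TRUE, length(tt))
  else tt >= window[1] & tt <= window[2]
  if (!any(keep)) stop("empty window", call. = FALSE)
  mean(trace$sd[keep])
}

#' Zero-motion score
#'
#' Largest absolute posterior mean over the trace, normalized by the true
#' peak speed. Near zero when the agent's estimate "remains at zero" despite
#' real motion — the signature of untreated BVP during passive movement.
#'
#' @param trace A `posterior_trace`.
#' @param truth A `velocity_series` with a nonzero peak.
#' @return Dimensionless score >= 0.
#' @export
zero_motion_score <- function(trace, truth) {
  stopifnot(inherits(trace, "posterior_trace"),
            inherits(truth, "velocity_series"),
            same_grid(trace$grid, truth$grid))
  peak <- max(abs(truth$values))
  if (peak == 0) stop("truth peak is zero", call. = FALSE)
  max(abs(trace$mean)) / peak
}

#' Full metrics report for one run
#'
#' @param trace A `posterior_trace`.
#' @param truth The true `velocity_series`.
#' @param max_lag Passed to [response_lag()].
#' @param window Movement window for [mean_uncertainty()]; `NULL` for the
#'   whole trace.
#' @return One-row `data.frame` with columns `peak_gain`,
#'   `displacement_gain`, `lag_s`, `mean_uncertainty`, `zero_motion_score`
#'   and `direction_correct` (`displacement_gain > 0`).
#' @export
metrics_report <- function(trace, truth, max_lag = 0.3, window = NULL) {
  g <- perceived_gain(trace, truth)
  lag <- suppressWarnings(response_lag(trace, truth, max_lag))
  data.frame(
    peak_gain = g$peak_gain,
    displacement_gain = g$displacement_gain,
    lag_s = as.numeric(lag),
    mean_uncertainty = mean_uncertainty(trace, window),
    zero_motion_score = zero_motion_score(trace, truth),
    direction_correct = g$displacement_gain > 0
  )
}
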