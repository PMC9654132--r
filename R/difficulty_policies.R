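#' Difficulty-policy configuration
#'
#' Describes how task speed (asteroid velocity, pixels/second) evolves over
#' a session under the three experimental conditions:
#'
#' * `constant` — 6 p/s for the 12-s initial phase, then a fixed mid-level
#'   speed (30 p/s by default; overridden when yoked to an adaptive group's
#'   realised mean speed).
#' * `time_ramp` — initial phase, then +2 p/s every 5 s.
#' * `stress_adaptive` — initial phase, then once per controller tick the
#'   speed is lowered by 2 p/s when the stress score exceeds +0.5, raised by
#'   2 p/s when it drops below -0.5, and left alone in the dead zone.
#'
#' Thresholds are strict inequalities (a score of exactly 0.5 does not
#' trigger).  All emitted speeds are clamped to `[min_speed, max_speed]`.
#'
#' @param policy One of `"constant"`, `"time_ramp"`, `"stress_adaptive"`.
#' @param initial_speed Speed during the initial phase, p/s (default 6).
#' @param initial_phase_seconds Length of the initial phase (default 12).
#' @param constant_speed Post-phase speed of the constant policy (default
#'   30; set to a yoked value to match an adaptive group's mean).
#' @param ramp_step,ramp_interval_seconds Time-ramp increment (default
#'   2 p/s every 5 s).
#' @param stress_high,stress_low Adaptation thresholds on the stress score
#'   (defaults +0.5 / -0.5).
#' @param adapt_step Adaptation increment, p/s (default 2).
#' @param adapt_interval_seconds Controller tick (default 1 s, so repeated
#'   steps move on the same scale as the 2 p/s-per-5-s ramp).
#' @param min_speed,max_speed Clamp bounds, p/s (defaults 2 and 200).
#' @return A list of class `policy_config`.
#' @export
policy_config <- function(policy = c("constant", "time_ramp",
                                     "stress_adaptive"),
                          initial_speed = 6, initial_phase_seconds = 12,
                          constant_speed = 30,
                          ramp_step = 2, ramp_interval_seconds = 5,
                          stress_high = 0.5, stress_low = -0.5,
                          adapt_step = 2, adapt_interval_seconds = 1,
                          min_speed = 2, max_speed = 200) {
  policy <- match.arg(policy)
  if (stress_low >= stress_high)
    sat_error("stress_low must be below stress_high", "sat_config_error")
  if (min_speed <= 0 || max_speed <= min_speed)
    sat_error("need 0 < min_speed < max_speed", "sat_config_error")
  if (min_speed > initial_speed)
    sat_error("min_speed must not exceed initial_speed", "sat_config_error")
  if (any(c(initial_speed, constant_speed, ramp_step, ramp_interval_seconds,
            adapt_step, adapt_interval_seconds) <= 0))
    sat_error("speeds, steps and intervals must be positive",
              "sat_config_error")
  structure(list(policy = policy, initial_speed = initial_speed,
                 initial_phase_seconds = initial_phase_seconds,
                 constant_speed = constant_speed, ramp_step = ramp_step,
                 ramp_interval_seconds = ramp_interval_seconds,
                 stress_high = stress_high, stress_low = stress_low,
                 adapt_step = adapt_step,
                 adapt_interval_seconds = adapt_interval_seconds,
                 min_speed = min_speed, max_speed = max_speed),
            class = "policy_config")
}

#' Read a policy configuration from a YAML file
#'
#' The file's keys mirror the [policy_config()] argument names.
#'
#' @param path Path to a YAML file.
#' @return A [policy_config()].
#' @export
read_policy_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    sat_error("the yaml package is required to read YAML configs",
              "sat_config_error")
  do.call(policy_config, yaml::read_yaml(path))
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Constant-policy speed at a time point
#'
#' @param t Time in seconds from session start (vectorised, >= 0).
#' @param config A [policy_config()].
#' @return Speed in p/s.
#' @export
speed_constant <- function(t, config = policy_config("constant")) {
  if (any(t < 0)) sat_error("t must be non-negative", "sat_input_error")
  out <- ifelse(t < config$initial_phase_seconds,
                config$initial_speed, config$constant_speed)
  .clamp(out, config$min_speed, config$max_speed)
}

#' Time-ramp policy speed at a time point
#'
#' After the initial phase the speed starts from `initial_speed` and gains
#' `ramp_step` p/s for every completed `ramp_interval_seconds`, capped at
#' `max_speed`.
#'
#' @inheritParams speed_constant
#' @return Speed in p/s.
#' @export
speed_time_ramp <- function(t, config = policy_config("time_ramp")) {
  if (any(t < 0)) sat_error("t must be non-negative", "sat_input_error")
  phase <- config$initial_phase_seconds
  ramped <- config$initial_speed +
    config$ramp_step * floor((t - phase) / config$ramp_interval_seconds)
  out <- ifelse(t < phase, config$initial_speed, ramped)
  .clamp(out, config$min_speed, config$max_speed)
}

#' One stress-adaptive controller step
#'
#' Lower the speed by `adapt_step` when the stress score is above
#' `stress_high`, raise it by `adapt_step` when below `stress_low`,
#' otherwise leave it unchanged; clamp to `[min_speed, max_speed]`.
#'
#' @param s Stress score (finite).
#' @param speed Current speed, p/s.
#' @param config A [policy_config()].
#' @return The new speed, p/s.
#' @export
adaptive_step <- function(s, speed, config = policy_config("stress_adaptive")) {
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s))
    sat_error("stress score must be a single finite number", "sat_input_error")
  new <- speed
  if (s > config$stress_high) new <- speed - config$adapt_step
  else if (s < config$stress_low) new <- speed + config$adapt_step
  .clamp(new, config$min_speed, config$max_speed)
}

#' Run a difficulty policy over a session
#'
#' Produces the piecewise-constant speed trace sampled at controller ticks
#' (`adapt_interval_seconds` apart, from t = 0).  The adaptive policy holds
#' `initial_speed` through the initial phase and while the estimator is
#' still warming up (no stress sample available), then applies
#' [adaptive_step()] once per tick using the most recent stress score
#' strictly before the tick.
#'
#' @param config A [policy_config()].
#' @param stress_stream For the adaptive policy, a data frame with columns
#'   `t` and `s` (e.g. from [batch_stress()]); ignored otherwise.
#' @param duration Session length in seconds.
#' @return A data frame of class `difficulty_trace` with columns `t` and
#'   `speed`.
#' @export
run_policy <- function(config, stress_stream = NULL, duration) {
  stopifnot(inherits(config, "policy_config"))
  if (duration <= 0) sat_error("duration must be positive", "sat_input_error")
  ticks <- seq(0, duration, by = config$adapt_interval_seconds)
  ticks <- ticks[ticks < duration]
  if (config$policy == "constant") {
    speed <- speed_constant(ticks, config)
  } else if (config$policy == "time_ramp") {
    speed <- speed_time_ramp(ticks, config)
  } else {
    if (is.null(stress_stream))
      sat_error("stress_stream is required for the stress_adaptive policy",
                "sat_config_error")
    speed <- numeric(length(ticks))
    cur <- config$initial_speed
    # index of the most recent stress sample strictly before each tick
    last_idx <- findInterval(ticks - 1e-9, stress_stream$t)
    for (i in seq_along(ticks)) {
      if (ticks[i] >= config$initial_phase_seconds && last_idx[i] > 0L) {
        cur <- adaptive_step(stress_stream$s[last_idx[i]], cur, config)
      }
      speed[i] <- cur
    }
  }
  difficulty_trace(ticks, speed)
}

#' Construct a difficulty trace
#'
#' @param t Tick times in seconds (increasing).
#' @param speed Speed at each tick, p/s; the trace is piecewise constant,
#'   each speed holding until the next tick.
#' @return A data frame of class `difficulty_trace`.
#' @export
difficulty_trace <- function(t, speed) {
  if (length(t) != length(speed))
    sat_error("t and speed must have the same length", "sat_format_error")
  if (length(t) > 1L && any(diff(t) <= 0))
    sat_error("t must be strictly increasing", "sat_validation_error")
  structure(data.frame(t = as.numeric(t), speed = as.numeric(speed)),
            class = c("difficulty_trace", "data.frame"))
}
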