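#' Synthetic-trainee parameters
#'
#' The generative model for a closed-loop synthetic trainee:
#'
#' * latent stress follows mean-reverting (Ornstein-Uhlenbeck) dynamics with
#'   reversion rate `theta`, diffusion scale `sigma`, and an equilibrium of
#'   `kappa * (speed - speed_ref)` while on task (0 at rest) — stress rises
#'   with task speed;
#' * grip force at the sampling rate is `g0 + g1 * latent + N(0, gnoise)`,
#'   clamped at 0 (a sensor cannot read negative force) — force is a noisy
#'   linear readout of stress;
#' * hits form an inhomogeneous Poisson stream with rate
#'   `h_max * exp(-(latent - s_opt)^2 / (2 u_width^2)) * (1 - exp(-t/tau_learn))`
#'   (inverted-U in stress, saturating learning in cumulative task time);
#' * life losses are Poisson with rate
#'   `loss_base * (speed / speed_ref) * (2 - (1 - exp(-t/tau_learn)))`
#'   (faster asteroids are harder to dodge; novices lose twice as often).
#'
#' @param s_opt Optimal latent stress (default 0).
#' @param u_width Width of the inverted-U (default 1.0).
#' @param h_max Peak hit rate, events/s (default 1.2).
#' @param loss_base Baseline life-loss rate per second at `speed_ref`
#'   (default 0.005).
#' @param speed_ref Reference speed, p/s (default 30).
#' @param tau_learn Learning time constant, seconds (default 240).
#' @param theta Stress mean-reversion rate, 1/s (default 0.1).
#' @param sigma Stress diffusion scale (default 0.3).
#' @param kappa Stress sensitivity to speed above `speed_ref`, per p/s
#'   (default 0.04).
#' @param g0,g1 Grip-force intercept and slope on latent stress (defaults
#'   5.0 and 1.5, sensor units).
#' @param gnoise Force noise SD (default 0.2).
#' @return A list of class `trainee_params`.
#' @export
trainee_params <- function(s_opt = 0, u_width = 1.0, h_max = 1.2,
                           loss_base = 0.005, speed_ref = 30,
                           tau_learn = 240, theta = 0.1, sigma = 0.3,
                           kappa = 0.04, g0 = 5.0, g1 = 1.5, gnoise = 0.2) {
  if (u_width <= 0 || h_max <= 0 || loss_base <= 0 || speed_ref <= 0 ||
      theta <= 0 || gnoise <= 0 || tau_learn < 0 || sigma < 0 || kappa < 0)
    sat_error("trainee rates and scales must be positive", "sat_config_error")
  structure(list(s_opt = s_opt, u_width = u_width, h_max = h_max,
                 loss_base = loss_base, speed_ref = speed_ref,
                 tau_learn = tau_learn, theta = theta, sigma = sigma,
                 kappa = kappa, g0 = g0, g1 = g1, gnoise = gnoise),
            class = "trainee_params")
}

#' The standard session schedule
#'
#' Three ten-minute task periods, each preceded by a two-minute rest.
#'
#' @param n_sessions Number of task periods (default 3).
#' @param task_seconds Task length (default 600).
#' @param rest_seconds Rest length (default 120).
#' @return A data frame with columns `duration` (s) and `task` (logical).
#' @export
session_schedule <- function(n_sessions = 3, task_seconds = 600,
                             rest_seconds = 120) {
  data.frame(
    duration = rep(c(rest_seconds, task_seconds), n_sessions),
    task = rep(c(FALSE, TRUE), n_sessions)
  )
}

.sim_run <- function(params, policy, schedule, seed,
                     stress_cfg = stress_config(),
                     reset_at_rest = FALSE) {
  stopifnot(inherits(params, "trainee_params"),
            inherits(policy, "policy_config"))
  pol_code <- match(policy$policy, c("constant", "time_ramp",
                                     "stress_adaptive")) - 1L
  set.seed(as.integer(seed))
  raw <- sim_core_cpp(
    schedule$duration, as.integer(schedule$task),
    unlist(params, use.names = FALSE),
    c(pol_code, policy$initial_speed, policy$initial_phase_seconds,
      policy$constant_speed, policy$ramp_step, policy$ramp_interval_seconds,
      policy$stress_high, policy$stress_low, policy$adapt_step,
      policy$adapt_interval_seconds, policy$min_speed, policy$max_speed),
    c(stress_cfg$rate_hz, window_capacity(stress_cfg),
      round(stress_cfg$warmup_seconds * stress_cfg$rate_hz),
      stress_cfg$sd_floor),
    reset_at_rest)
  raw
}

.as_session_record <- function(raw, params, policy, schedule, seed,
                               condition, participant_id, rate_hz) {
  kinds <- c(rep("hit", length(raw$hit_t)),
             rep("life_loss", length(raw$loss_t)))
  seg_end <- cumsum(schedule$duration)
  structure(list(
    force = suppressWarnings(
      force_series(raw$t, raw$force, rate_hz = rate_hz)),
    events = event_log(c(raw$hit_t, raw$loss_t), kinds),
    speed = difficulty_trace(raw$speed_t, raw$speed),
    stress = data.frame(t = raw$t, s = raw$s),
    latent_stress = data.frame(t = raw$t, latent = raw$latent),
    segments = data.frame(start = seg_end - schedule$duration, end = seg_end,
                          task = schedule$task),
    mean_abs_latent_dev = raw$mean_abs_dev,
    condition = condition, participant_id = participant_id, seed = seed
  ), class = "session_record")
}

#' Simulate one closed-loop training session
#'
#' Runs the synthetic trainee under a difficulty policy for a single
#' uninterrupted task period.  In the `stress_adaptive` condition the speed
#' trace is driven by the streaming estimator and controller operating on
#' the simulated grip force (never on the hidden latent stress, which is
#' returned for inspection only).
#'
#' @param params A [trainee_params()].
#' @param policy A [policy_config()].
#' @param duration Session length in seconds (must exceed the policy's
#'   initial phase).
#' @param seed Integer RNG seed; the same seed reproduces the session
#'   exactly.
#' @param stress_cfg A [stress_config()] for the in-loop estimator.
#' @return A `session_record`: a list with elements `force`
#'   ([force_series()]), `events` ([event_log()]), `speed`
#'   ([difficulty_trace()]), `stress` (emitted scores), `latent_stress`
#'   (hidden ground truth), `segments`, `condition`, `participant_id`,
#'   `seed`.
#' @export
simulate_session <- function(params = trainee_params(),
                             policy = policy_config("stress_adaptive"),
                             duration = 600, seed = 1,
                             stress_cfg = stress_config()) {
  if (duration <= policy$initial_phase_seconds)
    sat_error("duration must exceed the initial phase", "sat_config_error")
  schedule <- data.frame(duration = duration, task = TRUE)
  raw <- .sim_run(params, policy, schedule, seed, stress_cfg)
  cond <- switch(policy$policy, constant = "control_constant",
                 time_ramp = "control_time",
                 stress_adaptive = "stress_adaptive")
  .as_session_record(raw, params, policy, schedule, seed, cond, 1L,
                     stress_cfg$rate_hz)
}

#' Simulate one participant's full visit
#'
#' Runs the standard schedule (three 10-min task periods, each preceded by a
#' 2-min rest) as one continuous timeline.  The estimator window persists
#' across rests by default (the 40-min window spans the whole ~36-min
#' visit); each task period restarts its policy at the initial phase.
#'
#' @inheritParams simulate_session
#' @param schedule A [session_schedule()].
#' @param participant_id Identifier stored in the record.
#' @param reset_at_rest If `TRUE`, the estimator window is cleared at each
#'   rest period instead of persisting.
#' @return A `session_record` (see [simulate_session()]).
#' @export
simulate_participant <- function(params = trainee_params(),
                                 policy = policy_config("stress_adaptive"),
                                 schedule = session_schedule(), seed = 1,
                                 stress_cfg = stress_config(),
                                 participant_id = 1L,
                                 reset_at_rest = FALSE) {
  raw <- .sim_run(params, policy, schedule, seed, stress_cfg, reset_at_rest)
  cond <- switch(policy$policy, constant = "control_constant",
                 time_ramp = "control_time",
                 stress_adaptive = "stress_adaptive")
  .as_session_record(raw, params, policy, schedule, seed, cond,
                     participant_id, stress_cfg$rate_hz)
}

#' Derive per-participant seeds from a master seed
#'
#' @param master_seed Integer master seed.
#' @param n Number of seeds.
#' @return An integer vector of length `n`, below 2^31.
#' @export
derive_seeds <- function(master_seed, n) {
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a three-condition cohort
#'
#' `n_per_condition` participants per condition, each running the full
#' standard schedule under their condition's policy, with per-participant
#' seeds derived deterministically from the master seed.  (Speed yoking of
#' the constant condition to the adaptive group belongs to the experiment
#' harness, [run_experiment()]; here each policy uses its own configuration
#' as given.)
#'
#' @param n_per_condition Participants per condition (>= 1).
#' @param params A [trainee_params()].
#' @param policies Named list of [policy_config()]s for conditions
#'   `control_constant`, `control_time`, `stress_adaptive`.
#' @param schedule A [session_schedule()].
#' @param seed Master seed.
#' @param stress_cfg A [stress_config()].
#' @return A list of `3 * n_per_condition` session records.
#' @export
simulate_cohort <- function(n_per_condition, params = trainee_params(),
                            policies = list(
                              control_constant = policy_config("constant"),
                              control_time = policy_config("time_ramp"),
                              stress_adaptive = policy_config("stress_adaptive")),
                            schedule = session_schedule(), seed = 1,
                            stress_cfg = stress_config()) {
  if (n_per_condition < 1)
    sat_error("n_per_condition must be >= 1", "sat_config_error")
  stopifnot(all(.sat_conditions %in% names(policies)))
  n_total <- 3L * n_per_condition
  seeds <- derive_seeds(seed, n_total)
  conds <- rep(.sat_conditions, each = n_per_condition)
  lapply(seq_len(n_total), function(i) {
    simulate_participant(params, policies[[conds[i]]], schedule,
                         seed = seeds[i], stress_cfg = stress_cfg,
                         participant_id = i)
  })
}

#' Map global event times to cumulative task time
#'
#' Rest periods produce no events; for learning-curve analysis events are
#' placed on a clock that runs only while on task.
#'
#' @param record A `session_record`.
#' @return An [event_log()] with times in cumulative task seconds.
#' @export
task_time_events <- function(record) {
  stopifnot(inherits(record, "session_record"))
  segs <- record$segments
  task_segs <- segs[segs$task, , drop = FALSE]
  offsets <- cumsum(c(0, task_segs$end - task_segs$start))
  tt <- rep(NA_real_, nrow(record$events))
  for (i in seq_len(nrow(task_segs))) {
    in_seg <- record$events$t >= task_segs$start[i] &
      record$events$t < task_segs$end[i]
    tt[in_seg] <- record$events$t[in_seg] - task_segs$start[i] + offsets[i]
  }
  keep <- !is.na(tt)
  event_log(tt[keep], record$events$kind[keep])
}
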