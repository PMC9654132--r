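#' Time-weighted mean task speed of adaptive sessions (yoking)
#'
#' Computes the time-weighted mean of the piecewise-constant speed traces
#' across the supplied sessions.  In the experiment protocol this value
#' becomes the constant-control speed of the same batch, so the average
#' difficulty is equalised between the adaptive and constant arms.
#'
#' The result is invariant to session order and to splitting sessions into
#' sub-segments: it is total speed-time integral over total task time.
#'
#' @param sessions A list of `session_record`s (or a single one), or a list
#'   of [difficulty_trace()]s together with `durations`.
#' @param durations Required when passing bare traces: total duration in
#'   seconds covered by each trace (the last speed holds to the end).
#' @return Mean speed in p/s.
#' @export
yoke_constant_speed <- function(sessions, durations = NULL) {
  if (inherits(sessions, c("session_record", "difficulty_trace")))
    sessions <- list(sessions)
  if (length(sessions) == 0L)
    sat_error("need at least one adaptive session to yoke",
              "sat_input_error")
  total_int <- 0
  total_time <- 0
  for (i in seq_along(sessions)) {
    x <- sessions[[i]]
    if (inherits(x, "session_record")) {
      segs <- x$segments[x$segments$task, , drop = FALSE]
      tr <- x$speed
      for (k in seq_len(nrow(segs))) {
        in_seg <- tr$t >= segs$start[k] & tr$t < segs$end[k]
        tt <- tr$t[in_seg]
        sp <- tr$speed[in_seg]
        if (!length(tt)) next
        w <- diff(c(tt, segs$end[k]))
        total_int <- total_int + sum(sp * w)
        total_time <- total_time + (segs$end[k] - tt[1L])
      }
    } else if (inherits(x, "difficulty_trace")) {
      if (is.null(durations))
        sat_error("durations must be given for bare difficulty traces",
                  "sat_input_error")
      dur <- durations[[i]]
      w <- diff(c(x$t, dur))
      total_int <- total_int + sum(x$speed * w)
      total_time <- total_time + (dur - x$t[1L])
    } else {
      sat_error("sessions must be session_record or difficulty_trace",
                "sat_input_error")
    }
  }
  total_int / total_time
}

#' Pearson product-moment correlation of per-participant means
#'
#' Used to validate grip force against heart rate: the mean of each index
#' is computed per participant and the two mean vectors correlated.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The correlation coefficient r.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    sat_error("x and y must have equal length >= 3", "sat_input_error")
  if (var(x) == 0 || var(y) == 0)
    sat_error("correlation undefined: zero variance", "sat_degenerate")
  cor(x, y)
}

#' Per-participant training outcomes from a simulated record
#'
#' Maps events to cumulative task time, builds the learning curve, extracts
#' the first-derivative cutoff, and computes the realised mean task speed.
#'
#' @param record A `session_record`.
#' @param grid_seconds Learning-curve grid (default 1 s).
#' @param slope_fraction,smoother_bandwidth Passed to [find_cutoff()].
#' @return One-row data frame: `participant_id`, `condition`,
#'   `time_to_criterion`, `performance_at_criterion` (both `NA` if no
#'   cutoff exists), `mean_speed`, `n_hits`, `n_losses`.
#' @export
session_outcomes <- function(record, grid_seconds = 1, slope_fraction = 0.5,
                             smoother_bandwidth = 15) {
  stopifnot(inherits(record, "session_record"))
  ev <- task_time_events(record)
  task_total <- sum(record$segments$end[record$segments$task] -
                      record$segments$start[record$segments$task])
  curve <- suppressWarnings(
    build_curve(ev, grid_seconds, end_time = task_total))
  cp <- tryCatch(
    find_cutoff(curve, slope_fraction, smoother_bandwidth),
    sat_error = function(e) list(time_to_criterion = NA_real_,
                                 performance_at_criterion = NA_real_))
  data.frame(
    participant_id = record$participant_id,
    condition = record$condition,
    time_to_criterion = cp$time_to_criterion,
    performance_at_criterion = cp$performance_at_criterion,
    mean_speed = yoke_constant_speed(record),
    n_hits = sum(ev$kind == "hit"),
    n_losses = sum(ev$kind == "life_loss"),
    stringsAsFactors = FALSE
  )
}

#' Build an outcome table for a set of records
#'
#' @param records List of `session_record`s.
#' @param ... Passed to [session_outcomes()].
#' @return A data frame, one row per participant.
#' @export
outcome_table <- function(records, ...) {
  do.call(rbind, lapply(records, session_outcomes, ...))
}

#' Compare the three conditions on a training outcome
#'
#' Fits the fixed-effects linear model `outcome ~ condition` (with one
#' outcome value per participant this is the estimable core of a
#' mixed-model analysis) and reports the omnibus condition F test plus the
#' planned contrast of the stress-adaptive condition against the two
#' pooled controls (coded adaptive = +1, each control = -1/2).
#'
#' @param table An outcome table (see [outcome_table()]) with columns
#'   `condition` and the chosen outcome; rows with `NA` outcomes are
#'   dropped.
#' @param outcome `"time_to_criterion"` or `"performance_at_criterion"`
#'   (any numeric column is accepted).
#' @param covariates Optional character vector of additional covariate
#'   columns entered as fixed effects.
#' @return A list of class `comparison_result`: `f_stat`, `f_df`,
#'   `p_omnibus`, `t_adaptive`, `p_contrast`, `estimate_contrast` (adaptive
#'   mean minus pooled-control mean), `adj_r2`, `n_per_condition`, `n_used`.
#' @export
compare_conditions <- function(table,
                               outcome = c("time_to_criterion",
                                           "performance_at_criterion"),
                               covariates = NULL) {
  outcome <- if (is.character(outcome)) outcome[1L] else outcome
  if (!outcome %in% names(table))
    sat_error(paste0("no column ", outcome, " in the table"),
              "sat_format_error")
  keep <- !is.na(table[[outcome]]) & table$condition %in% .sat_conditions
  tab <- table[keep, , drop = FALSE]
  counts <- table(factor(tab$condition, levels = .sat_conditions))
  if (any(counts < 2L))
    sat_error("need at least 2 usable participants per condition",
              "sat_insufficient_data")
  y <- tab[[outcome]]
  if (var(y) == 0) {
    # a constant outcome carries no condition information
    return(structure(list(
      outcome = outcome, f_stat = 0, f_df = c(2L, nrow(tab) - 3L),
      p_omnibus = 1, t_adaptive = 0, p_contrast = 1, estimate_contrast = 0,
      adj_r2 = 0, n_per_condition = as.integer(counts), n_used = nrow(tab)
    ), class = "comparison_result"))
  }
  cond <- factor(tab$condition, levels = .sat_conditions)
  # planned contrast: stress_adaptive vs the mean of the two controls,
  # plus the orthogonal complement between the two controls
  c1 <- ifelse(cond == "stress_adaptive", 1, -0.5)
  c2 <- ifelse(cond == "control_constant", 1,
               ifelse(cond == "control_time", -1, 0))
  dat <- data.frame(y = y, c1 = c1, c2 = c2)
  form <- y ~ c1 + c2
  if (!is.null(covariates)) {
    for (cv in covariates) dat[[cv]] <- tab[[cv]]
    form <- stats::reformulate(c("c1", "c2", covariates), response = "y")
  }
  fit <- lm(form, data = dat)
  reduced <- if (is.null(covariates)) lm(y ~ 1, data = dat)
             else lm(stats::reformulate(covariates, response = "y"),
                     data = dat)
  an <- anova(reduced, fit)
  f_stat <- an$F[2L]
  f_df <- c(an$Df[2L], an$Res.Df[2L])
  p_omnibus <- an$`Pr(>F)`[2L]
  cf <- summary(fit)$coefficients
  t_adaptive <- cf["c1", "t value"]
  p_contrast <- cf["c1", "Pr(>|t|)"]
  # coefficient on c1 is (adaptive - pooled controls) / 1.5
  est <- 1.5 * cf["c1", "Estimate"]
  if (!is.finite(t_adaptive) && est == 0) {
    # all groups identical: no effect rather than 0/0
    t_adaptive <- 0
    p_contrast <- 1
  }
  adj_r2 <- summary(fit)$adj.r.squared
  if (!is.finite(adj_r2)) adj_r2 <- 0
  if (!is.finite(f_stat) && est == 0) {
    f_stat <- 0
    p_omnibus <- 1
  }
  structure(list(
    outcome = outcome, f_stat = f_stat, f_df = f_df, p_omnibus = p_omnibus,
    t_adaptive = t_adaptive, p_contrast = p_contrast,
    estimate_contrast = est, adj_r2 = adj_r2,
    n_per_condition = as.integer(counts), n_used = nrow(tab)
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Condition effect on %s\n", x$outcome))
  cat(sprintf("  omnibus F(%d,%d) = %.3f, p = %.4f, adj R^2 = %.3f\n",
              x$f_df[1L], x$f_df[2L], x$f_stat, x$p_omnibus, x$adj_r2))
  cat(sprintf("  stress-adaptive vs pooled controls: delta = %.3f, t = %.3f, p = %.4f\n",
              x$estimate_contrast, x$t_adaptive, x$p_contrast))
  cat(sprintf("  n used = %d (%s)\n", x$n_used,
              paste(x$n_per_condition, collapse = "/")))
  invisible(x)
}

#' Run a full three-arm in-silico training experiment
#'
#' Executes the batch protocol: participants are split into batches; in
#' each batch the stress-adaptive third runs first, the batch's constant
#' condition is then yoked to the adaptive group's realised mean speed, and
#' the control participants run.  Learning-curve outcomes are extracted per
#' participant and both outcomes compared across conditions.
#'
#' @param n_per_condition Participants per condition (default 15, the
#'   design's minimum per-condition sample size).
#' @param params A [trainee_params()].
#' @param n_batches Number of batches (default 4).
#' @param schedule A [session_schedule()].
#' @param seed Master seed; the whole experiment is reproducible from it.
#' @param stress_cfg A [stress_config()].
#' @param policies Named list of baseline [policy_config()]s; the constant
#'   policy's speed is overridden per batch by yoking unless `yoke = FALSE`.
#' @param yoke Yoke the constant condition to the adaptive mean speed
#'   (default `TRUE`).
#' @param slope_fraction,smoother_bandwidth Passed to [find_cutoff()].
#' @return A list of class `sat_experiment`: `outcomes` (data frame),
#'   `comparisons` (list with both outcomes' `comparison_result`s, `NULL`
#'   where not estimable), `yoked_speeds` (per batch), `seed`.
#' @export
run_experiment <- function(n_per_condition = 15, params = trainee_params(),
                           n_batches = 4, schedule = session_schedule(),
                           seed = 1, stress_cfg = stress_config(),
                           policies = list(
                             control_constant = policy_config("constant"),
                             control_time = policy_config("time_ramp"),
                             stress_adaptive = policy_config("stress_adaptive")),
                           yoke = TRUE,
                           slope_fraction = 0.5, smoother_bandwidth = 15) {
  stopifnot(all(.sat_conditions %in% names(policies)))
  n_batches <- min(n_batches, n_per_condition)
  per_batch <- diff(floor(seq(0, n_per_condition, length.out = n_batches + 1)))
  seeds <- derive_seeds(seed, 3L * n_per_condition)
  seed_i <- 0L
  next_seed <- function() {
    seed_i <<- seed_i + 1L
    seeds[seed_i]
  }
  pid <- 0L
  outcomes <- list()
  yoked_speeds <- numeric(n_batches)
  for (b in seq_len(n_batches)) {
    nb <- per_batch[b]
    if (nb == 0L) next
    # adaptive third first
    adaptive <- lapply(seq_len(nb), function(i) {
      simulate_participant(params, policies$stress_adaptive, schedule,
                           seed = next_seed(), stress_cfg = stress_cfg,
                           participant_id = pid + i)
    })
    pid <- pid + nb
    yk <- yoke_constant_speed(adaptive)
    yoked_speeds[b] <- yk
    const_pol <- policies$control_constant
    if (yoke)
      const_pol$constant_speed <- min(max(yk, const_pol$min_speed),
                                      const_pol$max_speed)
    controls <- vector("list", 2L * nb)
    for (i in seq_len(nb)) {
      controls[[i]] <- simulate_participant(
        params, const_pol, schedule, seed = next_seed(),
        stress_cfg = stress_cfg, participant_id = pid + i)
    }
    pid <- pid + nb
    for (i in seq_len(nb)) {
      controls[[nb + i]] <- simulate_participant(
        params, policies$control_time, schedule, seed = next_seed(),
        stress_cfg = stress_cfg, participant_id = pid + i)
    }
    pid <- pid + nb
    batch_out <- outcome_table(c(adaptive, controls),
                               slope_fraction = slope_fraction,
                               smoother_bandwidth = smoother_bandwidth)
    batch_out$batch <- b
    outcomes[[b]] <- batch_out
  }
  outcomes <- do.call(rbind, outcomes)
  cmp <- lapply(
    c(time_to_criterion = "time_to_criterion",
      performance_at_criterion = "performance_at_criterion"),
    function(oc) tryCatch(compare_conditions(outcomes, oc),
                          sat_error = function(e) NULL))
  structure(list(outcomes = outcomes, comparisons = cmp,
                 yoked_speeds = yoked_speeds,
                 n_per_condition = n_per_condition, seed = seed),
            class = "sat_experiment")
}
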