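#' Configuration for the moving z-score stress estimator
#'
#' The stress score is the z-score of the current grip-force sample against
#' the simple moving average (SMA) and simple moving standard deviation
#' (SMSD, population divisor) of a trailing window capped at
#' `window_seconds`.  With the defaults (40 min at 20 Hz) the window holds at
#' most 48,000 samples.  No score is emitted until `warmup_seconds` of
#' history have accumulated, mirroring the constant-speed initial phase of a
#' training session.
#'
#' @param rate_hz Sampling rate in Hz (default 20).
#' @param window_seconds Cap of the moving window in seconds (default 2400,
#'   i.e. 40 minutes).
#' @param sd_floor Small positive guard used in place of SMSD when the
#'   window is (numerically) constant (default 1e-9).  A constant grip
#'   carries no information, so the score is 0 there rather than an error:
#'   the controller must keep running in real time.
#' @param warmup_seconds History required before a score is emitted
#'   (default 12).
#' @return A list of class `stress_config`.
#' @export
stress_config <- function(rate_hz = 20, window_seconds = 2400,
                          sd_floor = 1e-9, warmup_seconds = 12) {
  if (rate_hz <= 0 || window_seconds <= 0 || sd_floor <= 0)
    sat_error("rate_hz, window_seconds and sd_floor must be positive",
              "sat_config_error")
  if (warmup_seconds > window_seconds)
    sat_error("warmup_seconds must not exceed window_seconds",
              "sat_config_error")
  structure(list(rate_hz = rate_hz, window_seconds = window_seconds,
                 sd_floor = sd_floor, warmup_seconds = warmup_seconds),
            class = "stress_config")
}

#' Maximum number of samples held by the stress window
#'
#' @param config A [stress_config()].
#' @return `round(window_seconds * rate_hz)` as an integer; 48,000 for the
#'   default 40-minute window at 20 Hz.
#' @export
window_capacity <- function(config = stress_config()) {
  stopifnot(inherits(config, "stress_config"))
  n <- round(config$window_seconds * config$rate_hz)
  if (n < 1) sat_error("window shorter than one sample", "sat_config_error")
  as.integer(n)
}

#' Create a fresh streaming stress-estimator state
#'
#' The state is an environment mutated in place by [stress_update()], which
#' keeps streaming updates O(1) without copying the ring buffer.  It holds
#' the retained samples (at most the window capacity), running sum and
#' sum-of-squares accumulators (re-summed exactly at regular intervals to
#' bound floating-point drift), and the current SMA/SMSD/score.
#'
#' @param config A [stress_config()].
#' @return An environment of class `stress_state`.
#' @export
new_stress_state <- function(config = stress_config()) {
  cap <- window_capacity(config)
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$cap <- cap
  st$buffer <- numeric(cap)   # ring buffer, slot `head` is next write
  st$head <- 1L
  st$count <- 0L
  st$n_seen <- 0L
  st$running_sum <- 0
  st$running_sumsq <- 0
  st$resync_every <- 4096L
  st$sma <- NA_real_
  st$smsd <- NA_real_
  st$s <- NA_real_
  class(st) <- "stress_state"
  st
}

#' The stress score formula
#'
#' `(cgf - sma) / max(smsd, sd_floor)`: the moving z-score of the current
#' grip force against the window statistics.
#'
#' @param cgf Current grip-force value.
#' @param sma Simple moving average of the window.
#' @param smsd Simple moving standard deviation (population divisor).
#' @param sd_floor Guard used when `smsd` is smaller (default 1e-9).
#' @return The stress score.
#' @export
stress_score <- function(cgf, sma, smsd, sd_floor = 1e-9) {
  (cgf - sma) / pmax(smsd, sd_floor)
}

#' Streaming stress update
#'
#' Appends one grip-force sample to the window (evicting the oldest if the
#' window is full), updates SMA and SMSD, and returns the stress score.  The
#' current sample is part of the window when the statistics are computed.
#' Until `warmup_seconds * rate_hz` samples of prior history exist the
#' estimator is still warming up and `NA` is returned (the state is updated
#' regardless).
#'
#' @param state A [new_stress_state()] environment; modified in place.
#' @param cgf Finite grip-force value.
#' @return The stress score, or `NA_real_` while warming up.
#' @export
stress_update <- function(state, cgf) {
  stopifnot(inherits(state, "stress_state"))
  if (!is.numeric(cgf) || length(cgf) != 1L || !is.finite(cgf))
    sat_error("cgf must be a single finite number", "sat_input_error")
  warmed <- state$count >= round(state$config$warmup_seconds *
                                   state$config$rate_hz)
  if (state$count == state$cap) {
    old <- state$buffer[state$head]
    state$running_sum <- state$running_sum - old
    state$running_sumsq <- state$running_sumsq - old * old
  } else {
    state$count <- state$count + 1L
  }
  state$buffer[state$head] <- cgf
  state$head <- if (state$head == state$cap) 1L else state$head + 1L
  state$running_sum <- state$running_sum + cgf
  state$running_sumsq <- state$running_sumsq + cgf * cgf
  state$n_seen <- state$n_seen + 1L
  if (state$n_seen %% state$resync_every == 0L) {
    live <- if (state$count == state$cap) state$buffer
            else state$buffer[seq_len(state$count)]
    state$running_sum <- sum(live)
    state$running_sumsq <- sum(live * live)
  }
  m <- state$count
  sma <- state$running_sum / m
  v <- state$running_sumsq / m - sma * sma
  smsd <- sqrt(max(v, 0))
  state$sma <- sma
  state$smsd <- smsd
  if (!warmed) {
    state$s <- NA_real_
    return(NA_real_)
  }
  state$s <- stress_score(cgf, sma, smsd, state$config$sd_floor)
  state$s
}

#' Offline stress computation for a recorded force series
#'
#' Applies the streaming estimator sample-by-sample to a whole series and
#' returns the emitted scores.  Identical values to calling
#' [stress_update()] in a loop; runs in compiled code.
#'
#' @param series A [force_series()] (or a bare numeric vector of forces
#'   sampled at `config$rate_hz`).
#' @param config A [stress_config()].
#' @return A data frame with columns `t` and `s`, one row per emitted score
#'   (empty, with a warning, if the series is shorter than the warm-up).
#' @export
batch_stress <- function(series, config = stress_config()) {
  if (inherits(series, "force_series")) {
    f <- series$force
    tt <- series$t
  } else {
    f <- as.numeric(series)
    tt <- (seq_along(f) - 1) / config$rate_hz
  }
  s <- stream_stress_cpp(f, window_capacity(config),
                         round(config$warmup_seconds * config$rate_hz),
                         config$sd_floor)
  keep <- !is.na(s)
  if (!any(keep)) {
    warning("series shorter than the estimator warm-up; no scores emitted",
            call. = FALSE)
    return(data.frame(t = numeric(), s = numeric()))
  }
  data.frame(t = tt[keep], s = s[keep])
}
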