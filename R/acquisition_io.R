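#' Construct a grip-force time series
#'
#' A `force_series` holds timestamped grip-force samples in sensor units.
#' Times are session-relative seconds (t = 0 at session start) and must be
#' strictly increasing; forces must be finite and non-negative.  If the
#' median inter-sample gap deviates from `1/rate_hz` by more than 10% a
#' validation warning is raised (stress windows assume a fixed sample count
#' per second).
#'
#' @param t Numeric vector of sample times in seconds, strictly increasing.
#' @param force Numeric vector of grip-force values (finite, >= 0), same
#'   length as `t`.
#' @param rate_hz Nominal sampling rate in Hz (default 20).
#' @return A data frame of class `force_series` with columns `t` and `force`
#'   and a `rate_hz` attribute.
#' @examples
#' fs <- force_series(seq(0, 1, by = 0.05), rexp(21) + 1)
#' @export
force_series <- function(t, force, rate_hz = 20) {
  t <- as.numeric(t)
  force <- as.numeric(force)
  if (length(t) != length(force))
    sat_error("t and force must have the same length", "sat_format_error")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) ||
      rate_hz <= 0)
    sat_error("rate_hz must be a positive number", "sat_config_error")
  if (length(t) > 1L && any(diff(t) <= 0))
    sat_error("t must be strictly increasing", "sat_validation_error")
  if (any(!is.finite(force)))
    sat_error("force values must be finite", "sat_validation_error")
  if (any(force < 0))
    sat_error("force values must be non-negative", "sat_validation_error")
  if (length(t) > 1L) {
    gap <- median(diff(t))
    if (abs(gap - 1 / rate_hz) > 0.1 / rate_hz)
      warning(sprintf(
        "median inter-sample gap %.4fs deviates >10%% from nominal 1/%g s",
        gap, rate_hz), call. = FALSE)
  }
  structure(data.frame(t = t, force = force),
            rate_hz = rate_hz,
            class = c("force_series", "data.frame"))
}

#' Construct a hit / life-loss event log
#'
#' @param t Numeric vector of event times in seconds, non-decreasing after
#'   sorting.
#' @param kind Character vector, each element `"hit"` or `"life_loss"`.
#' @return A data frame of class `event_log` with columns `t` and `kind`,
#'   sorted by `t`.
#' @export
event_log <- function(t = numeric(), kind = character()) {
  t <- as.numeric(t)
  kind <- as.character(kind)
  if (length(t) != length(kind))
    sat_error("t and kind must have the same length", "sat_format_error")
  bad <- setdiff(unique(kind), c("hit", "life_loss"))
  if (length(bad))
    sat_error(paste0("unknown event kind: ", paste(bad, collapse = ", ")),
              "sat_format_error")
  if (any(!is.finite(t)))
    sat_error("event times must be finite", "sat_validation_error")
  o <- order(t)
  structure(data.frame(t = t[o], kind = kind[o]),
            class = c("event_log", "data.frame"))
}

#' Construct a heart-rate series
#'
#' @param t Numeric vector of sample times in seconds.
#' @param hr Heart rate in beats per minute (finite, > 0).
#' @param rate_hz Nominal sampling rate (default 64).
#' @return A data frame of class `hr_series` with columns `t` and `hr`.
#' @export
hr_series <- function(t, hr, rate_hz = 64) {
  t <- as.numeric(t)
  hr <- as.numeric(hr)
  if (length(t) != length(hr))
    sat_error("t and hr must have the same length", "sat_format_error")
  if (length(t) > 1L && any(diff(t) <= 0))
    sat_error("t must be strictly increasing", "sat_validation_error")
  if (any(!is.finite(hr)) || any(hr <= 0))
    sat_error("hr must be finite and > 0", "sat_validation_error")
  structure(data.frame(t = t, hr = hr),
            rate_hz = rate_hz,
            class = c("hr_series", "data.frame"))
}

.read_csv_checked <- function(path, cols) {
  if (!file.exists(path))
    sat_error(paste0("file not found: ", path), "sat_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(cols %in% names(df)))
    sat_error(sprintf("expected columns %s in %s",
                      paste(cols, collapse = ","), path),
              "sat_format_error")
  df
}

#' Read a grip-force CSV
#'
#' Expects a header line `t,force` with times in seconds.  Rows whose force
#' value is missing or non-finite are rejected; the number rejected is
#' reported via a warning and stored in the `n_rejected` attribute so no row
#' is ever dropped silently.
#'
#' @param path Path to a CSV file with columns `t` and `force`.
#' @param rate_hz Nominal sampling rate in Hz (default 20).
#' @return A [force_series()] (attribute `n_rejected` counts dropped rows).
#' @export
read_force_series <- function(path, rate_hz = 20) {
  df <- .read_csv_checked(path, c("t", "force"))
  force <- suppressWarnings(as.numeric(df$force))
  keep <- is.finite(force)
  n_rej <- sum(!keep)
  if (n_rej > 0)
    warning(sprintf("%d row(s) with non-finite force rejected", n_rej),
            call. = FALSE)
  out <- force_series(df$t[keep], force[keep], rate_hz = rate_hz)
  attr(out, "n_rejected") <- n_rej
  out
}

#' Write a grip-force CSV
#'
#' Values are written with six decimal places so that
#' `read_force_series(write_force_series(x))` round-trips to 1e-6.
#'
#' @param series A [force_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_force_series <- function(series, path) {
  stopifnot(inherits(series, "force_series"))
  lines <- c("t,force",
             sprintf("%.6f,%.6f", series$t, series$force))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) sat_error(paste0("cannot write: ", path), "sat_io_error")
  invisible(path)
}

#' Read an event-log CSV
#'
#' Expects columns `t,kind` with `kind` in `{hit, life_loss}`.  Rows are
#' returned sorted by time.
#'
#' @param path Path to a CSV file.
#' @return An [event_log()].
#' @export
read_event_log <- function(path) {
  df <- .read_csv_checked(path, c("t", "kind"))
  event_log(df$t, df$kind)
}

#' Write an event-log CSV
#' @param events An [event_log()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  stopifnot(inherits(events, "event_log"))
  lines <- c("t,kind", sprintf("%.6f,%s", events$t, events$kind))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) sat_error(paste0("cannot write: ", path), "sat_io_error")
  invisible(path)
}

#' Read a heart-rate CSV
#' @param path Path to a CSV file with columns `t` and `hr`.
#' @param rate_hz Nominal sampling rate (default 64).
#' @return An [hr_series()].
#' @export
read_hr_series <- function(path, rate_hz = 64) {
  df <- .read_csv_checked(path, c("t", "hr"))
  hr_series(df$t, df$hr, rate_hz = rate_hz)
}

#' Resample a force series onto its nominal regular grid
#'
#' Linear interpolation onto the grid `seq(min(t), max(t), by = 1/rate_hz)`.
#' Resampling is always explicit: no other operation interpolates.
#'
#' @param series A [force_series()], possibly irregularly sampled.
#' @param rate_hz Target rate; defaults to the series' nominal rate.
#' @return A regularly sampled [force_series()].
#' @export
resample_force_series <- function(series, rate_hz = attr(series, "rate_hz")) {
  stopifnot(inherits(series, "force_series"))
  if (nrow(series) < 2L)
    sat_error("need at least 2 samples to resample", "sat_validation_error")
  grid <- seq(series$t[1L], series$t[nrow(series)], by = 1 / rate_hz)
  f <- approx(series$t, series$force, xout = grid)$y
  suppressWarnings(force_series(grid, f, rate_hz = rate_hz))
}
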