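#' Performance score
#'
#' The natural logarithm of cumulative hits minus ten times cumulative life
#' losses, `ln(hits - 10 * losses)`.  Where the argument is not positive the
#' score is undefined and returned as `NA` (early play routinely has
#' `10 * losses >= hits`; the log simply does not exist there).
#'
#' @param cum_hits,cum_losses Non-negative integer counts (vectorised).
#' @return Numeric vector of scores, `NA` where undefined.
#' @examples
#' performance_score(100, 2)  # log(80)
#' @export
performance_score <- function(cum_hits, cum_losses) {
  if (any(cum_hits < 0) || any(cum_losses < 0))
    sat_error("counts must be non-negative", "sat_input_error")
  if (any(cum_hits != round(cum_hits)) || any(cum_losses != round(cum_losses)))
    sat_error("counts must be integers", "sat_input_error")
  arg <- cum_hits - 10 * cum_losses
  ifelse(arg > 0, log(pmax(arg, 1e-300)), NA_real_)
}

#' Construct a learning curve
#'
#' @param t Time grid in seconds (increasing).
#' @param score Performance score at each grid point (`NA` where undefined).
#' @return A data frame of class `learning_curve`.
#' @export
learning_curve <- function(t, score) {
  if (length(t) != length(score))
    sat_error("t and score must have the same length", "sat_format_error")
  if (length(t) > 1L && any(diff(t) <= 0))
    sat_error("t must be strictly increasing", "sat_validation_error")
  structure(data.frame(t = as.numeric(t), score = as.numeric(score)),
            class = c("learning_curve", "data.frame"))
}

#' Build a learning curve from an event log
#'
#' Cumulative hit and life-loss counts are evaluated on a uniform grid
#' (1-s steps by default) and [performance_score()] is applied pointwise.
#' Grid points where the score is undefined are kept, flagged as `NA`.
#'
#' @param events An [event_log()].
#' @param grid_seconds Grid step in seconds (default 1).
#' @param end_time Last grid time; defaults to the latest event time
#'   rounded up to the grid.
#' @return A [learning_curve()] with attributes `n_hits` and `n_losses`.
#' @export
build_curve <- function(events, grid_seconds = 1, end_time = NULL) {
  stopifnot(inherits(events, "event_log"))
  if (nrow(events) == 0L) {
    warning("empty event log: learning curve is entirely undefined",
            call. = FALSE)
    end_time <- if (is.null(end_time)) 0 else end_time
  } else if (is.null(end_time)) {
    end_time <- ceiling(max(events$t) / grid_seconds) * grid_seconds
  }
  grid <- seq(0, end_time, by = grid_seconds)
  ht <- sort(events$t[events$kind == "hit"])
  lt <- sort(events$t[events$kind == "life_loss"])
  cum_h <- findInterval(grid, ht)
  cum_l <- findInterval(grid, lt)
  out <- learning_curve(grid, performance_score(cum_h, cum_l))
  attr(out, "n_hits") <- length(ht)
  attr(out, "n_losses") <- length(lt)
  out
}

# Centered moving average whose half-width shrinks symmetrically at the
# ends, so the first and last points are left untouched rather than biased
# toward the interior.
.smooth_ma <- function(y, half) {
  n <- length(y)
  if (half < 1L) return(y)
  cs <- cumsum(y)
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    lo <- i - h
    hi <- i + h
    out[i] <- (cs[hi] - if (lo > 1L) cs[lo - 1L] else 0) / (hi - lo + 1L)
  }
  out
}

# Central finite differences (one-sided at the ends).
.fd_slope <- function(y, t) {
  n <- length(y)
  d <- numeric(n)
  if (n >= 3L) {
    d[2:(n - 1L)] <- (y[3:n] - y[1:(n - 2L)]) / (t[3:n] - t[1:(n - 2L)])
  }
  d[1L] <- (y[2L] - y[1L]) / (t[2L] - t[1L])
  d[n] <- (y[n] - y[n - 1L]) / (t[n] - t[n - 1L])
  d
}

#' First-derivative cutoff of a learning curve
#'
#' Smooths the defined portion of the curve (centered moving average),
#' takes the first derivative (central finite differences), finds the
#' maximum slope, and returns the first grid point after the maximum where
#' the slope has fallen to `slope_fraction` of that maximum.  The cutoff's
#' x-value is the time-to-criterion, its y-value (the smoothed score) the
#' performance-at-criterion.
#'
#' Undefined (`NA`) stretches of the curve are excluded rather than
#' imputed; the longest contiguous run of defined points is analysed (for
#' well-behaved curves that is simply everything after the undefined
#' prefix).
#'
#' @param curve A [learning_curve()] with at least 10 defined points.
#' @param slope_fraction Fraction of the maximum slope defining the cutoff
#'   (default 0.5).  With `slope_fraction >= 1` the cutoff is the slope
#'   maximum itself.
#' @param smoother_bandwidth Moving-average bandwidth in seconds
#'   (default 15).
#' @return A list of class `cutoff_point` with elements
#'   `time_to_criterion` and `performance_at_criterion`.
#' @export
find_cutoff <- function(curve, slope_fraction = 0.5,
                        smoother_bandwidth = 15) {
  stopifnot(inherits(curve, "learning_curve"))
  def <- !is.na(curve$score)
  if (!any(def))
    sat_error("learning curve is entirely undefined", "sat_input_error")
  runs <- rle(def)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  def_runs <- which(runs$values)
  best <- def_runs[which.max(runs$lengths[def_runs])]
  idx <- starts[best]:ends[best]
  if (length(idx) < 10L)
    sat_error("need at least 10 defined points in the learning curve",
              "sat_input_error")
  tt <- curve$t[idx]
  grid_step <- median(diff(tt))
  half <- max(0L, round(smoother_bandwidth / grid_step / 2))
  y <- .smooth_ma(curve$score[idx], half)
  d <- .fd_slope(y, tt)
  imax <- which.max(d)
  smax <- d[imax]
  thr <- slope_fraction * smax
  if (thr >= smax) {
    j <- imax
  } else {
    after <- which(d[(imax + 1L):length(d)] <= thr)
    if (imax == length(d) || length(after) == 0L)
      sat_error("slope never falls below the criterion fraction: no knee",
                "sat_no_knee")
    j <- imax + after[1L]
  }
  structure(list(time_to_criterion = tt[j],
                 performance_at_criterion = y[j]),
            class = "cutoff_point")
}
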