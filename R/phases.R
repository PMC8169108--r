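#' Low-pass filtered derivative of the tangential force magnitude
#'
#' The in-plane tangential force magnitude is low-pass filtered (zero-phase
#' Butterworth, default 10 Hz cutoff) and differentiated with central
#' differences (one-sided at the ends). The filter keeps 1 kHz measurement
#' noise from dominating the derivative used for phase segmentation.
#'
#' @param trace a `force_trace`.
#' @param cutoff_hz low-pass cutoff in Hz; 0 disables filtering.
#' @return Numeric series of dF_t/dt (N/s) on the trace's time base.
#' @export
tangential_force_derivative <- function(trace, cutoff_hz = 10) {
  mag <- sqrt(trace$tangential_x^2 + trace$tangential_y^2)
  n <- length(mag)
  if (n < 2L) stop("at least two samples are required")
  if (cutoff_hz > 0 && n > 12) {
    bf <- signal::butter(2, cutoff_hz / (trace$signal_rate / 2))
    # reflect-pad to suppress the filter's edge transients
    p <- min(n - 1L, 1000L)
    padded <- c(2 * mag[1] - mag[(p + 1):2],
                mag,
                2 * mag[n] - mag[(n - 1):(n - p)])
    mag <- signal::filtfilt(bf, padded)[(p + 1):(p + n)]
  }
  dt <- 1 / trace$signal_rate
  d <- numeric(n)
  d[2:(n - 1)] <- (mag[3:n] - mag[1:(n - 2)]) / (2 * dt)
  d[1] <- (mag[2] - mag[1]) / dt
  d[n] <- (mag[n] - mag[n - 1]) / dt
  d
}

#' Locate the forward and backward movement windows
#'
#' Movement start and end are found from the plate-position velocity along
#' the trial's movement axis, thresholded at 10% of the commanded speed.
#'
#' @param trace a `force_trace` with plate position.
#' @param cfg the [trial_config()] of the trial (gives direction and speed);
#'   defaults to the config attached to the trace.
#' @param threshold_frac velocity threshold as a fraction of commanded speed.
#' @return list with `forward` and `backward` windows, each `c(start, end)`
#'   in seconds.
#' @export
segment_movements <- function(trace, cfg = attr(trace, "config"),
                              threshold_frac = 0.1) {
  if (is.null(cfg)) stop("a trial_config is required (trace carries none)")
  ax <- direction_axis(cfg$direction)
  pos <- trace$plate_x * ax[1] + trace$plate_y * ax[2]
  n <- length(pos)
  dt <- 1 / trace$signal_rate
  v <- c(diff(pos), 0) / dt
  thr <- threshold_frac * cfg$tangential_speed
  moving <- abs(v) > thr
  if (!any(moving)) stop("no movement detected in the plate position trace")
  r <- rle(moving)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs) < 2L)
    stop("expected a forward and a backward movement; found ", length(runs))
  w <- function(k) c(trace$time[starts[k]], trace$time[ends[k]])
  list(forward = w(runs[1]), backward = w(runs[2]))
}

#' Segment one movement into onset, partial-slip and plateau phases
#'
#' The onset phase is the first 100 ms of the movement. The partial-slip
#' phase lasts until the tangential force plateau: the first time after the
#' onset at which the low-pass-filtered tangential force derivative stays
#' below `epsilon` times its in-movement peak for at least `sustain` seconds
#' (the derivative "returning close to zero"). The plateau phase is the
#' remainder of the movement. If the criterion is never met the partial-slip
#' phase extends to the movement end, the plateau is empty, and a warning is
#' raised.
#'
#' @param trace a `force_trace`.
#' @param window movement window `c(start, end)` from [segment_movements()].
#' @param movement label, "forward" or "backward".
#' @param epsilon derivative threshold as a fraction of the in-movement peak.
#' @param sustain time (s) the derivative must stay below threshold.
#' @param cutoff_hz passed to [tangential_force_derivative()].
#' @param onset_duration onset length in seconds (100 ms).
#' @return An object of class `movement_phases` with `onset`, `partial_slip`
#'   and `plateau` windows, `full_slip_time` and the movement `window`.
#' @export
segment_phases <- function(trace, window, movement = "forward",
                           epsilon = 0.05, sustain = 0.05, cutoff_hz = 10,
                           onset_duration = 0.1) {
  if (diff(window) < 2 * onset_duration)
    stop("movement window must be at least ", 2 * onset_duration, " s")
  d <- abs(tangential_force_derivative(trace, cutoff_hz = cutoff_hz))
  t <- trace$time
  in_win <- t >= window[1] & t <= window[2]
  onset_end <- window[1] + onset_duration
  peak <- max(d[in_win])
  full_slip <- NA_real_
  if (peak > 0) {
    idx <- which(in_win & t > onset_end)
    below <- d[idx] < epsilon * peak
    need <- max(1L, round(sustain * trace$signal_rate))
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- which(r$values & r$lengths >= need)
    # the sustained run must also not be interrupted before the window end:
    if (length(k) > 0) full_slip <- t[idx[starts[k[1]]]]
  }
  if (is.na(full_slip)) {
    warning("tangential force derivative never settled; plateau is empty")
    full_slip <- window[2]
  }
  structure(list(movement = movement,
                 onset = c(window[1], onset_end),
                 partial_slip = c(onset_end, full_slip),
                 plateau = c(full_slip, window[2]),
                 full_slip_time = full_slip,
                 window = window),
            class = "movement_phases")
}

#' Segment both movements of a trial into phases
#'
#' Convenience wrapper running [segment_movements()] and [segment_phases()]
#' for the forward and backward movements of one trial.
#'
#' @param trial a trial from [generate_dataset()], or a `force_trace`.
#' @param ... passed to [segment_phases()].
#' @return list with elements `forward` and `backward` ([segment_phases()]
#'   results).
#' @export
trial_phases <- function(trial, ...) {
  trace <- if (inherits(trial, "force_trace")) trial else trial$forces
  mv <- segment_movements(trace)
  list(forward = segment_phases(trace, mv$forward, "forward", ...),
       backward = segment_phases(trace, mv$backward, "backward", ...))
}

#' Indices of 20 ms strain bins inside the partial-slip phase
#'
#' A bin belongs to the partial-slip phase when its start time lies in
#' `[onset_end, full_slip_time)`.
#'
#' @param phases a `movement_phases` object.
#' @param bin_times start times of the strain bins (seconds).
#' @return Integer vector of bin indices.
#' @export
partial_slip_bins <- function(phases, bin_times) {
  which(bin_times >= phases$partial_slip[1] &
        bin_times < phases$partial_slip[2])
}
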