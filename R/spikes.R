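#' Spike train at 1 ms resolution
#'
#' @param times spike times in seconds; strictly increasing, nonnegative,
#'   with at most one spike per 1 ms sample.
#' @param duration record duration in seconds.
#' @param resolution sampling resolution in seconds (default 1 ms).
#' @param waveform_pp optional per-spike peak-to-peak amplitudes (for SNR).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, duration, resolution = 1e-3,
                        waveform_pp = NULL) {
  times <- as.numeric(times)
  if (any(times < 0)) stop("spike times must be nonnegative")
  if (is.unsorted(times, strictly = TRUE)) stop("spike times must be strictly increasing")
  if (length(times) > 1 && any(diff(times) < resolution - 1e-9))
    stop("at most one spike per ", resolution * 1e3, " ms sample is allowed")
  if (missing(duration)) duration <- if (length(times)) max(times) else 0
  structure(list(times = times, duration = duration, resolution = resolution,
                 n = length(times), waveform_pp = waveform_pp),
            class = "spike_train")
}

#' Instantaneous firing rate (inverse inter-spike interval)
#'
#' Between consecutive spikes at t_i and t_{i+1}, the rate 1/(t_{i+1} - t_i)
#' is assigned over the interval (t_i, t_{i+1}]; the series is zero before
#' the first interval and after the last spike. Resampled at `rate` Hz.
#'
#' @param spikes a [spike_train()].
#' @param duration record duration (defaults to the train's).
#' @param rate output sampling rate, Hz.
#' @return Numeric rate series (spikes/s) at `rate` Hz, with attribute
#'   `times`.
#' @export
instantaneous_rate <- function(spikes, duration = spikes$duration,
                               rate = 1000) {
  t <- seq(0, duration, by = 1 / rate)
  out <- numeric(length(t))
  st <- spikes$times
  if (length(st) >= 2L) {
    isi_rate <- 1 / diff(st)
    # sample falls in interval (st[i], st[i+1]] -> rate isi_rate[i]
    k <- findInterval(t, st, left.open = TRUE)
    ok <- k >= 1L & k <= length(isi_rate)
    out[ok] <- isi_rate[k[ok]]
  }
  attr(out, "times") <- t
  out
}

# MATLAB-style Gaussian window: w(i) = exp(-(alpha * i / (N/2))^2 / 2) for
# i = -(N-1)/2 ... (N-1)/2, i.e. sigma = (N-1)/(2*alpha) samples
gausswin <- function(n = 480, alpha = 6) {
  i <- seq(-(n - 1) / 2, (n - 1) / 2)
  exp(-0.5 * (alpha * i / ((n - 1) / 2))^2)
}

#' Gaussian-smoothed firing rate
#'
#' The 1 kHz binary spike vector is convolved with a unit-sum Gaussian window
#' (480 points, alpha 6, i.e. sigma about 40 ms) and scaled by 1000, giving a
#' rate in spikes/s whose time integral equals the spike count for interior
#' spikes. The rate is then resampled to the imaging frame rate (50 Hz) by
#' frame-aligned decimation.
#'
#' @param spikes a [spike_train()].
#' @param duration record duration in seconds.
#' @param n_window,alpha Gaussian window length (samples) and shape.
#' @param signal_rate input resolution, Hz.
#' @param frame_rate output rate, Hz.
#' @param keep_1khz also return the full-resolution rate.
#' @return An object of class `smoothed_rate`: `rate` (spikes/s at
#'   `frame_rate`), `times`, the `window_spec`, and optionally `rate_1khz`.
#' @export
smoothed_rate <- function(spikes, duration = spikes$duration, n_window = 480,
                          alpha = 6, signal_rate = 1000, frame_rate = 50,
                          keep_1khz = FALSE) {
  n <- ceiling(duration * signal_rate)
  x <- numeric(n)
  idx <- floor(spikes$times * signal_rate + 1e-7) + 1L
  idx <- idx[idx >= 1L & idx <= n]
  x[idx] <- x[idx] + 1
  w <- gausswin(n_window, alpha)
  w <- w / sum(w)
  y <- stats::filter(x, w, method = "convolution", sides = 2)
  y[is.na(y)] <- 0                       # window hanging over the record ends
  y <- as.numeric(y) * signal_rate
  step <- signal_rate / frame_rate
  keep <- seq(1L, n, by = step)
  structure(list(rate = y[keep], times = (keep - 1L) / signal_rate,
                 frame_rate = frame_rate,
                 window_spec = list(n = n_window, alpha = alpha,
                                    normalization = "unit-sum"),
                 rate_1khz = if (keep_1khz) y else NULL),
            class = "smoothed_rate")
}

#' Spike counts in 20 ms frame bins
#'
#' Bins are half-open `[start, start + width)`: a spike exactly on a bin
#' boundary is assigned to the later bin.
#'
#' @param spikes a [spike_train()].
#' @param bin_times bin start times in seconds (defaults to 20 ms bins over
#'   the record).
#' @param bin_width bin width in seconds.
#' @return Integer counts per bin, with attribute `times`.
#' @export
bin_spikes <- function(spikes, bin_times = NULL, bin_width = 0.02) {
  if (is.null(bin_times))
    bin_times <- seq(0, max(spikes$duration - bin_width, 0), by = bin_width)
  k <- findInterval(spikes$times, c(bin_times, bin_times[length(bin_times)] +
                                      bin_width))
  k <- k[spikes$times >= bin_times[1] &
           spikes$times < bin_times[length(bin_times)] + bin_width]
  counts <- tabulate(k, nbins = length(bin_times))
  attr(counts, "times") <- bin_times
  counts
}

#' Fraction of trials with activity in a phase window
#'
#' @param spike_trains list of [spike_train()] objects, one per trial.
#' @param windows list of `c(start, end)` windows (one per trial) or a single
#'   window recycled to all trials.
#' @return Fraction of trials containing at least one spike in the window.
#' @export
fraction_active <- function(spike_trains, windows) {
  if (length(spike_trains) == 0L) stop("no trials")
  if (!is.list(windows)) windows <- rep(list(windows), length(spike_trains))
  active <- mapply(function(spk, w)
    any(spk$times >= w[1] & spk$times <= w[2]), spike_trains, windows)
  mean(active)
}

#' Spike recording signal-to-noise ratio
#'
#' `(mean peak-to-peak spike amplitude - mean peak-to-peak noise) / mean
#' peak-to-peak noise`, i.e. the noise level is subtracted from the spike
#' signal before taking the ratio.
#'
#' @param spike_pp,noise_pp peak-to-peak amplitude samples.
#' @return The SNR (scalar).
#' @export
spike_snr <- function(spike_pp, noise_pp) {
  if (length(spike_pp) == 0L || length(noise_pp) == 0L)
    stop("both amplitude sets must be non-empty")
  mn <- mean(noise_pp)
  if (mn <= 0) stop("mean peak-to-peak noise must be positive")
  (mean(spike_pp) - mn) / mn
}
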