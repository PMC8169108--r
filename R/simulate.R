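#' Tracked feature trajectories
#'
#' Container for per-frame 2D pixel positions of N tracked skin features at
#' the imaging frame rate. Reference positions are the first-frame positions.
#'
#' @param x,y N x T matrices of pixel coordinates (features x frames).
#' @param frame_rate imaging frame rate in Hz.
#' @param contact_mask optional N x T logical matrix of in-contact flags;
#'   defaults to all `TRUE`.
#' @return An object of class `feature_trajectories`.
#' @export
feature_trajectories <- function(x, y, frame_rate = 50, contact_mask = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) stop("x and y must have identical dimensions")
  if (nrow(x) < 3L) stop("at least 3 features are required")
  if (is.null(contact_mask)) {
    contact_mask <- matrix(TRUE, nrow(x), ncol(x))
  } else if (!all(dim(contact_mask) == dim(x))) {
    stop("contact_mask must match the trajectory dimensions")
  }
  structure(list(x = x, y = y, frame_rate = frame_rate,
                 reference_positions = cbind(x[, 1], y[, 1]),
                 contact_mask = contact_mask,
                 n_features = nrow(x), n_frames = ncol(x)),
            class = "feature_trajectories")
}

# Timeline of one trial: stationary hold, forward movement, hold, backward
# movement, final hold. All times in seconds from trial start.
trial_timeline <- function(cfg, pre_hold = 0.3, mid_hold = 0.3,
                           post_hold = 0.3) {
  fwd_dur <- cfg$forward_amplitude / cfg$tangential_speed
  bwd_dur <- cfg$backward_amplitude / cfg$tangential_speed
  t_fwd <- pre_hold
  t_mid <- t_fwd + fwd_dur
  t_bwd <- t_mid + mid_hold
  t_end <- t_bwd + bwd_dur
  list(t_fwd_start = t_fwd, t_fwd_end = t_mid,
       t_bwd_start = t_bwd, t_bwd_end = t_end,
       duration = t_end + post_hold)
}

# cumulative unsigned plate displacement (mm) of each movement at times t
plate_displacements <- function(t, tl, cfg) {
  v <- cfg$tangential_speed
  d_fwd <- pmin(pmax(t - tl$t_fwd_start, 0) * v, cfg$forward_amplitude)
  d_bwd <- pmin(pmax(t - tl$t_bwd_start, 0) * v, cfg$backward_amplitude)
  list(forward = d_fwd, backward = d_bwd)
}

#' Simulate feature trajectories with a traveling partial-slip front
#'
#' Each seeded feature follows the plate along the movement axis until the
#' cumulative plate displacement exceeds its radius-dependent slip threshold
#' `D(r)` (see [slip_wave_params()]), then holds its position: slip starts at
#' the contact periphery and sweeps inward, and once the center's threshold is
#' exceeded (full slip) all features are stationary, so strain rates vanish.
#' The backward movement starts from the strained forward end-state; a feature
#' re-sticks to the plate at reversal and slips again once displaced to
#' `-D(r)`. Displacement along the axis drives a transverse contraction with
#' ratio `wave$lateral_contraction`.
#'
#' @param geom a [contact_geometry()].
#' @param wave a [slip_wave_params()].
#' @param cfg a [trial_config()].
#' @return A [feature_trajectories()] with attributes `timeline`,
#'   `true_full_slip_times` (named seconds, NA when full slip is never
#'   reached), `geometry`, `wave` and `config`.
#' @export
simulate_feature_trajectories <- function(geom, wave, cfg) {
  if (!inherits(geom, "contact_geometry")) stop("geom must be a contact_geometry")
  if (!inherits(wave, "slip_wave_params")) stop("wave must be slip_wave_params")
  if (!inherits(cfg, "trial_config")) stop("cfg must be a trial_config")

  tl <- trial_timeline(cfg)
  t <- seq(0, tl$duration, by = 1 / cfg$frame_rate)
  d <- plate_displacements(t, tl, cfg)

  mu <- wave$friction_coefficient
  R <- geom$radius
  p <- wave$slip_onset_profile_exponent
  ref <- geom$features
  r <- sqrt((ref[, 1] - geom$center[1])^2 + (ref[, 2] - geom$center[2])^2)
  D <- wave$full_slip_displacement * mu * (1 - (r / R)^p)  # mm, per feature

  # displacement along the movement axis, mm; u[i, k] for feature i, frame k
  u_fwd <- outer(D, d$forward, pmin)              # stick then hold
  u_end <- u_fwd[, ncol(u_fwd)]
  u_bwd <- pmax(sweep(-outer(rep(1, length(D)), d$backward), 1, u_end, "+"),
                -D)                               # re-stick, slip at -D(r)
  moving_back <- d$backward > 0
  u <- u_fwd
  u[, moving_back] <- u_bwd[, moving_back]

  # transverse contraction proportional to axial displacement and signed
  # transverse offset from the movement axis
  ax <- direction_axis(cfg$direction)
  perp <- c(-ax[2], ax[1])
  s <- (ref[, 1] - geom$center[1]) * perp[1] +
       (ref[, 2] - geom$center[2]) * perp[2]      # px
  w <- -wave$lateral_contraction * u * (s / R)    # mm

  px <- 1 / geom$pixel_pitch                      # px per mm
  X <- ref[, 1] + (u * ax[1] + w * perp[1]) * px
  Y <- ref[, 2] + (u * ax[2] + w * perp[2]) * px

  D0 <- wave$full_slip_displacement * mu          # center threshold, mm
  fs_fwd <- if (mu == 0) tl$t_fwd_start
            else if (D0 < cfg$forward_amplitude)
              tl$t_fwd_start + D0 / cfg$tangential_speed else NA_real_
  d_bwd_center <- min(cfg$forward_amplitude, D0) + D0
  fs_bwd <- if (mu == 0) tl$t_bwd_start
            else if (d_bwd_center < cfg$backward_amplitude)
              tl$t_bwd_start + d_bwd_center / cfg$tangential_speed
            else NA_real_

  traj <- feature_trajectories(X, Y, frame_rate = cfg$frame_rate)
  attr(traj, "timeline") <- tl
  attr(traj, "true_full_slip_times") <- c(forward = fs_fwd, backward = fs_bwd)
  attr(traj, "geometry") <- geom
  attr(traj, "wave") <- wave
  attr(traj, "config") <- cfg
  traj
}

#' Simulate 1 kHz force and plate-position traces
#'
#' The normal force is held at the preset value (optionally with a
#' band-limited fluctuation); the tangential force follows a saturating
#' spring model `F_t = min(k x_plate, mu F_n)` with stiffness
#' `k = F_n / full_slip_displacement`, so the plateau at `mu * F_n` is reached
#' exactly at the trajectory generator's full-slip time. The trace is smoothed
#' with a zero-phase low-pass filter and optionally corrupted with Gaussian
#' measurement noise.
#'
#' @param wave a [slip_wave_params()].
#' @param cfg a [trial_config()].
#' @param noise_sd standard deviation of additive tangential force noise, N.
#' @param normal_fluctuation_amp RMS amplitude (N) of a band-limited (< 5 Hz)
#'   fluctuation added to the normal force; 0 disables it.
#' @param smoothing_cutoff_hz cutoff of the zero-phase low-pass applied to the
#'   ideal tangential trace.
#' @return An object of class `force_trace`: 1 kHz `time`, `normal`,
#'   `tangential_x`, `tangential_y`, `plate_x`, `plate_y`, `plate_z` (mm),
#'   with attributes `timeline` and `true_full_slip_times`.
#' @export
simulate_force_traces <- function(wave, cfg, noise_sd = 0,
                                  normal_fluctuation_amp = 0,
                                  smoothing_cutoff_hz = 20) {
  tl <- trial_timeline(cfg)
  t <- seq(0, tl$duration, by = 1 / cfg$signal_rate)
  d <- plate_displacements(t, tl, cfg)
  mu <- wave$friction_coefficient
  fn <- cfg$normal_force
  k <- fn / wave$full_slip_displacement          # N/mm

  f_fwd <- pmin(k * d$forward, mu * fn)
  f_end <- min(k * cfg$forward_amplitude, mu * fn)
  f <- ifelse(d$backward > 0, pmax(f_end - k * d$backward, -mu * fn), f_fwd)

  if (smoothing_cutoff_hz > 0 && mu > 0) {
    bf <- signal::butter(2, smoothing_cutoff_hz / (cfg$signal_rate / 2))
    f <- signal::filtfilt(bf, f)
  }

  set.seed(cfg$seed + 104729L)
  if (noise_sd > 0) f <- f + stats::rnorm(length(f), sd = noise_sd)
  normal <- rep(fn, length(t))
  if (normal_fluctuation_amp > 0) {
    bl <- signal::butter(2, 5 / (cfg$signal_rate / 2))
    z <- signal::filtfilt(bl, stats::rnorm(length(t)))
    normal <- normal + normal_fluctuation_amp * z / stats::sd(z)
  }

  ax <- direction_axis(cfg$direction)
  pos <- d$forward - d$backward                   # signed mm along axis
  mu_ <- mu  # full-slip times mirror the trajectory generator
  D0 <- wave$full_slip_displacement * mu_
  fs_fwd <- if (mu_ == 0) tl$t_fwd_start
            else if (D0 < cfg$forward_amplitude)
              tl$t_fwd_start + D0 / cfg$tangential_speed else NA_real_
  d_bwd_center <- min(cfg$forward_amplitude, D0) + D0
  fs_bwd <- if (mu_ == 0) tl$t_bwd_start
            else if (d_bwd_center < cfg$backward_amplitude)
              tl$t_bwd_start + d_bwd_center / cfg$tangential_speed
            else NA_real_

  structure(list(time = t, normal = normal,
                 tangential_x = f * ax[1], tangential_y = f * ax[2],
                 plate_x = pos * ax[1], plate_y = pos * ax[2],
                 plate_z = rep(-2, length(t)),
                 signal_rate = cfg$signal_rate),
            class = "force_trace",
            timeline = tl,
            true_full_slip_times = c(forward = fs_fwd, backward = fs_bwd),
            config = cfg)
}

#' Simulate an afferent spike train from a strain-rate series
#'
#' Draws an inhomogeneous Poisson spike train (by thinning at the 1 kHz
#' signal resolution, at most one spike per 1 ms sample) from the rectified
#' linear rate model of [afferent_ground_truth()], driven by the strain-rate
#' tensor at the afferent's receptive-field center.
#'
#' @param strain either a `strain_grid` (the tensor at `truth$rf_center` is
#'   extracted) or a T x 3 matrix of (exx, eyy, exy) in %/s at the frame rate,
#'   one row per 20 ms strain bin.
#' @param truth an [afferent_ground_truth()].
#' @param cfg a [trial_config()]; `cfg$seed` (offset per afferent by `id`)
#'   seeds the draw.
#' @param duration trial duration in seconds; inferred from `strain` if the
#'   bins carry times.
#' @param id integer offset so multiple afferents of one trial get
#'   independent streams.
#' @return A [spike_train()] with attribute `rate_1khz`, the generative rate.
#' @export
simulate_afferent_spikes <- function(strain, truth, cfg, duration = NULL,
                                     id = 0L) {
  if (inherits(strain, "strain_grid")) {
    cell <- grid_cell_index(truth$rf_center[1], truth$rf_center[2],
                            strain$nrow, strain$ncol)
    tensors <- cbind(strain$exx[cell, ], strain$eyy[cell, ],
                     strain$exy[cell, ])
    bin_times <- strain$times
  } else {
    tensors <- as.matrix(strain)
    if (ncol(tensors) != 3L) stop("strain series must have 3 columns")
    bin_times <- attr(strain, "times")
  }
  n_bins <- nrow(tensors)
  if (is.null(duration)) {
    duration <- if (!is.null(bin_times))
      max(bin_times) + 1 / cfg$frame_rate else n_bins / cfg$frame_rate
  }
  tensors[!is.finite(tensors)] <- 0   # out-of-contact: no measured drive

  rot <- rotate_tensor(tensors, truth$preferred_orientation)
  e_par <- rot[, 1]
  lambda <- truth$baseline_rate +
    truth$gain_compressive * pmax(-e_par, 0) +
    truth$gain_tensile * pmax(e_par, 0) +
    truth$gain_shear * abs(rot[, 3])
  lambda <- pmax(lambda, 0)

  # 1 kHz sample grid; each strain bin's rate holds for its 20 ms
  dt <- 1 / cfg$signal_rate
  n_samp <- ceiling(duration * cfg$signal_rate)
  samp_t <- (seq_len(n_samp) - 1L) * dt
  if (is.null(bin_times)) bin_times <- (seq_len(n_bins) - 1L) / cfg$frame_rate
  bin_of <- findInterval(samp_t, bin_times)
  rate <- numeric(n_samp)
  inside <- bin_of >= 1L & bin_of <= n_bins
  rate[inside] <- lambda[bin_of[inside]]

  set.seed(cfg$seed + 7L * as.integer(id) + 15485863L)
  p <- pmin(rate * dt, 1)
  fired <- stats::runif(n_samp) < p
  spk <- spike_train(samp_t[fired], duration = duration)
  attr(spk, "rate_1khz") <- rate
  spk
}

#' Generate a full synthetic experiment
#'
#' Runs the complete factorial design (2 frictions x 4 directions x
#' `repetitions`) of the tangential-loading protocol: feature trajectories
#' with the partial-slip front, force traces, and one spike train per
#' ground-truth afferent, all deterministically seeded from `master_seed`.
#' Afferent rates are driven by the strain-rate tensor interpolated at each
#' afferent's receptive-field grid cell from the trial's own mesh strains
#' (spatially smoothed and median filtered exactly as the analysis pipeline
#' does).
#'
#' @param truths list of [afferent_ground_truth()] objects.
#' @param master_seed integer master seed.
#' @param geom,wave_high,wave_low geometry and per-friction slip parameters.
#' @param repetitions repetitions per cell (default 5, the full 40-trial
#'   design).
#' @param noise_sd tangential force noise passed to [simulate_force_traces()].
#' @param normal_fluctuation_amp see [simulate_force_traces()].
#' @param cache_strains keep the (smoothed, median-filtered) per-triangle
#'   mesh strains on each trial so downstream analyses need not recompute
#'   them (costs memory, saves time).
#' @return An object of class `slip_dataset`: a list of trials (each with
#'   `trajectories`, `forces`, `spikes`, `config`, `true_full_slip_times`),
#'   plus the shared `mesh`, `geometry`, `truths` and `master_seed`.
#' @export
generate_dataset <- function(truths, master_seed = 1L,
                             geom = contact_geometry(),
                             wave_high = slip_wave_params(friction_coefficient = 1.0),
                             wave_low = slip_wave_params(friction_coefficient = 0.5),
                             repetitions = 5L, noise_sd = 0.005,
                             normal_fluctuation_amp = 0,
                             cache_strains = TRUE) {
  if (inherits(truths, "afferent_ground_truth")) truths <- list(truths)
  design <- expand.grid(repetition = seq_len(repetitions),
                        direction = c("ulnar", "distal", "radial", "proximal"),
                        friction = c("high", "low"),
                        stringsAsFactors = FALSE)

  gs <- strain_grid_spec()
  mesh <- NULL
  trials <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    seed_i <- (as.integer(master_seed) + 104729L * i) %% 2147483647L
    cfg <- trial_config(direction = design$direction[i],
                        friction = design$friction[i],
                        repetition = design$repetition[i], seed = seed_i)
    wave <- if (cfg$friction == "high") wave_high else wave_low
    traj <- simulate_feature_trajectories(geom, wave, cfg)
    if (is.null(mesh)) mesh <- delaunay_triangulate(traj)
    forces <- simulate_force_traces(wave, cfg, noise_sd = noise_sd,
                                    normal_fluctuation_amp = normal_fluctuation_amp)

    strains <- temporal_median_filter(
      smooth_mesh_strains(compute_green_lagrange_rates(traj, mesh), mesh))
    pts <- do.call(rbind, lapply(truths, function(tr)
      grid_cell_coords(tr$rf_center[1], tr$rf_center[2], gs)))
    series <- interpolate_at_points(strains, mesh, pts)

    spikes <- vector("list", length(truths))
    for (a in seq_along(truths)) {
      m <- cbind(series$exx[a, ], series$eyy[a, ], series$exy[a, ])
      attr(m, "times") <- strains$times
      spikes[[a]] <- simulate_afferent_spikes(m, truths[[a]], cfg,
                                              duration = attr(traj, "timeline")$duration,
                                              id = a)
    }
    trials[[i]] <- list(trajectories = traj, forces = forces, spikes = spikes,
                        config = cfg,
                        true_full_slip_times = attr(traj, "true_full_slip_times"),
                        mesh_strains = if (cache_strains) strains else NULL)
  }
  structure(list(trials = trials, mesh = mesh, geometry = geom,
                 truths = truths,
                 wave = list(high = wave_high, low = wave_low),
                 design = design, master_seed = as.integer(master_seed)),
            class = "slip_dataset")
}
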