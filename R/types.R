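#' Contact geometry with seeded tracking features
#'
#' Defines the circular fingerpad contact in image (pixel) coordinates and
#' seeds equally spaced features inside it on a square lattice. The image
#' frame follows the convention that x spans the radial-ulnar axis (ulnar to
#' the right) and y the proximal-distal axis (distal up).
#'
#' @param center numeric length 2, contact center in pixels.
#' @param radius contact radius in pixels; must be positive.
#' @param pixel_pitch mm per pixel (default 25.4/1200, i.e. 1200 dpi).
#' @param feature_spacing spacing of the seeded feature lattice in pixels.
#' @return An object of class `contact_geometry` with the seeded `features`
#'   (n x 2 matrix), the lattice spacing and the pixel scale.
#' @export
contact_geometry <- function(center = c(600, 450), radius = 300,
                             pixel_pitch = 25.4 / 1200,
                             feature_spacing = 24) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("contact radius must be a single positive number")
  if (length(center) != 2L || !all(is.finite(center)))
    stop("contact center must be two finite pixel coordinates")
  if (feature_spacing <= 0) stop("feature_spacing must be positive")
  if (pixel_pitch <= 0) stop("pixel_pitch must be positive")

  k <- floor(radius / feature_spacing)
  g <- seq(-k, k) * feature_spacing
  pts <- as.matrix(expand.grid(x = center[1] + g, y = center[2] + g))
  r <- sqrt((pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2)
  pts <- pts[r <= radius, , drop = FALSE]
  if (nrow(pts) < 3L)
    stop("degenerate geometry: fewer than 3 features fit inside the contact; ",
         "decrease feature_spacing or increase radius")
  # non-collinearity: lattice with >= 3 points in a disk is collinear only if
  # all points share a row/column
  if (length(unique(pts[, 1])) < 2L && length(unique(pts[, 2])) < 2L ||
      (length(unique(pts[, 1])) == 1L || length(unique(pts[, 2])) == 1L) &&
      nrow(pts) >= 3L && (length(unique(pts[, 1])) == 1L ||
                          length(unique(pts[, 2])) == 1L))
    stop("degenerate geometry: seeded features are collinear")

  structure(list(center = as.numeric(center), radius = radius,
                 pixel_pitch = pixel_pitch,
                 feature_spacing = feature_spacing,
                 n_features = nrow(pts), features = unname(pts)),
            class = "contact_geometry")
}

#' Parameters of the traveling partial-slip front
#'
#' The simulator uses a radial slip-threshold profile: a feature initially at
#' radius r (contact radius R) sticks to the plate until the cumulative plate
#' displacement exceeds
#' \deqn{D(r) = D_{full} \mu (1 - (r/R)^p),}
#' after which it stops following the plate. The threshold decreases strictly
#' with radius, so slip starts at the periphery and sweeps inward as an
#' annular front; the contact center slips last, at displacement
#' \eqn{D_{full}\mu}, which defines full slip. Lower friction scales every
#' threshold down and therefore produces earlier full slip.
#'
#' @param friction_coefficient dimensionless friction coefficient mu.
#' @param full_slip_displacement plate displacement (mm, per unit mu) at which
#'   the contact center slips; the actual center-slip displacement is
#'   `full_slip_displacement * friction_coefficient`.
#' @param slip_onset_profile_exponent shape exponent p of the radial profile.
#' @param lateral_contraction Poisson-like ratio coupling displacement along
#'   the movement axis to transverse contraction.
#' @return An object of class `slip_wave_params`.
#' @export
slip_wave_params <- function(friction_coefficient = 1.0,
                             full_slip_displacement = 3.0,
                             slip_onset_profile_exponent = 1.0,
                             lateral_contraction = 0.2) {
  if (friction_coefficient < 0) stop("friction coefficient must be >= 0")
  if (full_slip_displacement <= 0) stop("full_slip_displacement must be > 0")
  if (slip_onset_profile_exponent <= 0) stop("profile exponent must be > 0")
  structure(list(friction_coefficient = friction_coefficient,
                 full_slip_displacement = full_slip_displacement,
                 slip_onset_profile_exponent = slip_onset_profile_exponent,
                 lateral_contraction = lateral_contraction),
            class = "slip_wave_params")
}

#' Single-trial stimulation protocol
#'
#' One trial of the tangential-loading protocol: the plate, pressed at a
#' constant normal force, moves at constant speed in one of four directions
#' (forward movement), pauses, then moves back past the start (backward
#' movement). Defaults follow the stimulation protocol the analysis assumes:
#' 5.5 mm/s, 8 mm forward, 12 mm backward, 4 N normal force, 50 Hz imaging
#' and 1 kHz force/spike sampling.
#'
#' @param direction one of "ulnar", "distal", "radial", "proximal".
#' @param friction "high" or "low".
#' @param repetition repetition index (1-5 in the full design).
#' @param tangential_speed plate speed, mm/s.
#' @param forward_amplitude,backward_amplitude movement amplitudes in mm
#'   (0 is allowed and produces a no-stimulus trial).
#' @param normal_force preset normal force, N.
#' @param frame_rate imaging frame rate, Hz; must divide `signal_rate`.
#' @param signal_rate force/spike sampling rate, Hz.
#' @param seed integer RNG seed for this trial.
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(direction = c("ulnar", "distal", "radial", "proximal"),
                         friction = c("high", "low"), repetition = 1L,
                         tangential_speed = 5.5,
                         forward_amplitude = 8, backward_amplitude = 12,
                         normal_force = 4,
                         frame_rate = 50, signal_rate = 1000, seed = 1L) {
  direction <- match.arg(direction)
  friction <- match.arg(friction)
  if (tangential_speed <= 0) stop("tangential_speed must be positive")
  if (forward_amplitude < 0 || backward_amplitude < 0)
    stop("movement amplitudes must be >= 0")
  if (normal_force <= 0) stop("normal_force must be positive")
  if (frame_rate <= 0 || signal_rate <= 0 || signal_rate %% frame_rate != 0)
    stop("frame_rate must be positive and divide signal_rate")
  structure(list(direction = direction, friction = friction,
                 repetition = as.integer(repetition),
                 tangential_speed = tangential_speed,
                 forward_amplitude = forward_amplitude,
                 backward_amplitude = backward_amplitude,
                 normal_force = normal_force,
                 frame_rate = frame_rate, signal_rate = signal_rate,
                 seed = as.integer(seed)),
            class = "trial_config")
}

#' Ground-truth afferent used by the simulator
#'
#' A simulated afferent fires as an inhomogeneous Poisson process whose rate
#' is a rectified linear function of the local strain-rate tensor at its
#' receptive-field center, after rotating the tensor into the afferent's
#' preferred orientation:
#' \deqn{\lambda(t) = b + g_c [-e_\parallel]^+ + g_t [e_\parallel]^+ +
#'   g_s |e_{xy}'|}
#' where \eqn{e_\parallel} is the axial strain rate along the preferred
#' orientation (%/s) and gains are in spikes/s per %/s.
#'
#' @param rf_center receptive-field center as a grid cell `c(row, col)` of the
#'   90 x 120 strain grid.
#' @param rf_radius receptive-field radius in pixels (default 150).
#' @param preferred_orientation axis angle in degrees, in \[0, 180) (an
#'   orientation, not a direction: 90 means the proximal-distal axis).
#' @param gain_compressive,gain_tensile,gain_shear nonnegative gains.
#' @param baseline_rate baseline firing rate, spikes/s.
#' @param label informal class tag, e.g. "FA-like" or "SA-like".
#' @return An object of class `afferent_ground_truth`.
#' @export
afferent_ground_truth <- function(rf_center = c(50, 75), rf_radius = 150,
                                  preferred_orientation = 0,
                                  gain_compressive = 0, gain_tensile = 0,
                                  gain_shear = 0, baseline_rate = 0,
                                  label = "FA-like") {
  if (any(c(gain_compressive, gain_tensile, gain_shear) < 0))
    stop("gains must be nonnegative")
  if (rf_radius <= 0) stop("rf_radius must be positive")
  if (preferred_orientation < 0 || preferred_orientation >= 180)
    stop("preferred_orientation must lie in [0, 180)")
  if (baseline_rate < 0) stop("baseline_rate must be nonnegative")
  structure(list(rf_center = as.numeric(rf_center), rf_radius = rf_radius,
                 preferred_orientation = preferred_orientation,
                 gain_compressive = gain_compressive,
                 gain_tensile = gain_tensile, gain_shear = gain_shear,
                 baseline_rate = baseline_rate, label = label),
            class = "afferent_ground_truth")
}

#' Receptive field of a recorded afferent
#'
#' @param center receptive-field center in pixel coordinates `c(x, y)`.
#' @param radius radius in pixels; type I afferent fields are modeled as
#'   150-pixel disks.
#' @param relation_to_contact one of "inside", "border", "outside".
#' @return An object of class `receptive_field`.
#' @export
receptive_field <- function(center, radius = 150,
                            relation_to_contact = c("inside", "border",
                                                    "outside")) {
  relation_to_contact <- match.arg(relation_to_contact)
  if (radius <= 0) stop("radius must be positive")
  structure(list(center = as.numeric(center), radius = radius,
                 relation_to_contact = relation_to_contact),
            class = "receptive_field")
}

# direction -> unit vector in the image frame (x: radial-ulnar, ulnar right;
# y: proximal-distal, distal up)
direction_axis <- function(direction) {
  switch(direction,
         ulnar = c(1, 0), radial = c(-1, 0),
         distal = c(0, 1), proximal = c(0, -1),
         stop("unknown direction: ", direction))
}
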