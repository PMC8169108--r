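# Independent oracles used across the test files.

# principal strains by brute force: scan the axial strain over rotation
# angles and take the extrema
principal_oracle <- function(exx, eyy, exy, n_angles = 3600) {
  th <- seq(0, pi, length.out = n_angles + 1)[-(n_angles + 1)]
  ax <- exx * cos(th)^2 + eyy * sin(th)^2 + exy * sin(2 * th)
  list(e1 = min(ax), e2 = max(ax))
}

# Green-Lagrange strain rate from a known affine map F (2x2), closed form
gl_oracle <- function(F, fps = 50) {
  E <- 0.5 * (t(F) %*% F - diag(2))
  c(exx = E[1, 1], eyy = E[2, 2], exy = E[1, 2]) * fps * 100
}

# apply an affine map (2x2 matrix A, offset b) to points
apply_affine <- function(pts, A, b = c(0, 0)) {
  sweep(pts %*% t(A), 2, b, "+")
}

random_rotation <- function() {
  th <- stats::runif(1, 0, 2 * pi)
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# two-frame trajectories from reference points and an affine map
two_frame_traj <- function(pts, A, b = c(0, 0), frame_rate = 50) {
  q <- apply_affine(pts, A, b)
  feature_trajectories(x = cbind(pts[, 1], q[, 1]),
                       y = cbind(pts[, 2], q[, 2]), frame_rate = frame_rate)
}

# small scattered point cloud that triangulates well
scatter_points <- function(n = 25, seed = 1) {
  set.seed(seed)
  cbind(stats::runif(n, 0, 100), stats::runif(n, 0, 100))
}

# compact geometry for fast unit tests
tiny_geom <- function() contact_geometry(radius = 120, feature_spacing = 30)
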