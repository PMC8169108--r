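as_tensor_matrix <- function(t) {
  if (is.matrix(t)) {
    if (ncol(t) != 3L) stop("tensor matrix must have columns (exx, eyy, exy)")
    t
  } else {
    if (length(t) != 3L) stop("a strain tensor is (exx, eyy, exy)")
    matrix(t, 1, 3)
  }
}

#' Principal strains of a 2D symmetric strain tensor
#'
#' Eigenvalues of the tensor sorted ascending: `e1` is the (most compressive)
#' smaller eigenvalue and `e2` the larger (tensile) one, with
#' `e1 + e2 = exx + eyy`. The orientation of the e1 eigenvector is reported in
#' degrees in \[0, 180).
#'
#' @param t a length-3 vector `c(exx, eyy, exy)` or an n x 3 matrix.
#' @return A list with `e1`, `e2` and `orientation` (degrees).
#' @export
principal_strains <- function(t) {
  m <- as_tensor_matrix(t)
  tr2 <- (m[, 1] + m[, 2]) / 2
  dif <- (m[, 1] - m[, 2]) / 2
  rad <- sqrt(dif^2 + m[, 3]^2)
  # axial strain along angle a: tr2 + dif*cos(2a) + exy*sin(2a);
  # minimum at 2a = atan2(exy, dif) + pi
  ang <- (0.5 * atan2(m[, 3], dif) * 180 / pi + 90) %% 180
  list(e1 = tr2 - rad, e2 = tr2 + rad, orientation = ang)
}

#' Strain norm (rotation-invariant deformation intensity)
#'
#' `sqrt(exx^2 + eyy^2 + 2 exy^2)`: the Frobenius norm of the symmetric
#' tensor, with the shear counted twice under the square root. Invariant
#' under [rotate_tensor()].
#'
#' @inheritParams principal_strains
#' @return numeric vector of norms (NA propagates).
#' @export
strain_norm <- function(t) {
  m <- as_tensor_matrix(t)
  sqrt(m[, 1]^2 + m[, 2]^2 + 2 * m[, 3]^2)
}

#' Rotate a strain tensor into a rotated reference frame
#'
#' Applies `e' = R(theta) e R(theta)^T` with
#' `R(theta) = [[cos, sin], [-sin, cos]]`, so the rotated x-axis points along
#' the angle `theta` (in degrees) from the original x-axis; at `theta = 90`
#' the rotated x-axis is the original y-axis and the shear changes sign.
#'
#' @inheritParams principal_strains
#' @param theta rotation angle in degrees.
#' @return Tensor(s) in the same shape as the input.
#' @export
rotate_tensor <- function(t, theta) {
  m <- as_tensor_matrix(t)
  th <- theta * pi / 180
  cs <- cos(th); sn <- sin(th)
  exx <- cs^2 * m[, 1] + sn^2 * m[, 2] + 2 * cs * sn * m[, 3]
  eyy <- sn^2 * m[, 1] + cs^2 * m[, 2] - 2 * cs * sn * m[, 3]
  exy <- cs * sn * (m[, 2] - m[, 1]) + (cs^2 - sn^2) * m[, 3]
  out <- cbind(exx = exx, eyy = eyy, exy = exy)
  if (is.matrix(t)) out else drop(out)
}

#' Half-wave rectified tensor components
#'
#' Splits each component v into its nonnegative positive part `max(v, 0)`
#' (stretch / positive shear) and negative part `max(-v, 0)` (compression /
#' negative shear), so `v = pos - neg` and `pos * neg = 0`.
#'
#' @inheritParams principal_strains
#' @return An n x 6 matrix with columns `exx_pos, exx_neg, eyy_pos, eyy_neg,
#'   exy_pos, exy_neg` (a named length-6 vector for vector input).
#' @export
rectify_components <- function(t) {
  m <- as_tensor_matrix(t)
  out <- cbind(exx_pos = pmax(m[, 1], 0), exx_neg = pmax(-m[, 1], 0),
               eyy_pos = pmax(m[, 2], 0), eyy_neg = pmax(-m[, 2], 0),
               exy_pos = pmax(m[, 3], 0), exy_neg = pmax(-m[, 3], 0))
  if (is.matrix(t)) out else drop(out)
}

#' Derived scalar channel of a strain grid
#'
#' @param grid a `strain_grid`.
#' @param channel one of "norm", "e1", "e2", "exx", "eyy", "exy".
#' @return A (ncell x nbins) matrix of the requested channel.
#' @export
grid_channel <- function(grid, channel = c("norm", "e1", "e2",
                                           "exx", "eyy", "exy")) {
  channel <- match.arg(channel)
  switch(channel,
         exx = grid$exx, eyy = grid$eyy, exy = grid$exy,
         norm = sqrt(grid$exx^2 + grid$eyy^2 + 2 * grid$exy^2),
         e1 = {
           tr2 <- (grid$exx + grid$eyy) / 2
           tr2 - sqrt(((grid$exx - grid$eyy) / 2)^2 + grid$exy^2)
         },
         e2 = {
           tr2 <- (grid$exx + grid$eyy) / 2
           tr2 + sqrt(((grid$exx - grid$eyy) / 2)^2 + grid$exy^2)
         })
}
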