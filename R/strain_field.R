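#' Delaunay triangulation of the reference feature positions
#'
#' Triangulates the first-frame (reference) positions of the tracked features
#' and drops degenerate (near zero-area) triangles. Triangle adjacency
#' (sharing an edge) is computed for spatial smoothing.
#'
#' @param traj a [feature_trajectories()], or an n x 2 matrix of points.
#' @param degenerate_tol reference-area tolerance (px^2) below which a
#'   triangle is dropped.
#' @return An object of class `triangle_mesh`: `triangles` (ntri x 3 vertex
#'   indices), `neighbors` (ntri x 3, NA where no neighbor), `centroids`
#'   (reference coordinates), `areas`.
#' @export
delaunay_triangulate <- function(traj, degenerate_tol = 1e-6) {
  pts <- if (inherits(traj, "feature_trajectories"))
    traj$reference_positions else as.matrix(traj)
  if (nrow(pts) < 3L) stop("at least 3 points are required for triangulation")
  tm <- tryCatch(interp::tri.mesh(pts[, 1], pts[, 2]),
                 error = function(e)
                   stop("triangulation failed (collinear or degenerate ",
                        "points?): ", conditionMessage(e), call. = FALSE))
  if (tm$n != nrow(pts) || any(tm$x != pts[, 1]) || any(tm$y != pts[, 2]))
    stop("triangulation reordered or dropped points (duplicate features?)")
  tri <- interp::triangles(tm)[, 1:3, drop = FALSE]

  a <- triangle_areas(pts, tri)
  bad <- abs(a) < degenerate_tol
  if (any(bad)) {
    message(sum(bad), " degenerate triangle(s) dropped")
    tri <- tri[!bad, , drop = FALSE]
    a <- a[!bad]
  }
  if (nrow(tri) == 0L) stop("no non-degenerate triangles")

  centroids <- cbind((pts[tri[, 1], 1] + pts[tri[, 2], 1] + pts[tri[, 3], 1]) / 3,
                     (pts[tri[, 1], 2] + pts[tri[, 2], 2] + pts[tri[, 3], 2]) / 3)
  mesh <- structure(list(triangles = unname(tri),
                         neighbors = triangle_neighbors(tri),
                         centroids = unname(centroids), areas = abs(a),
                         points = unname(pts)),
                    class = "triangle_mesh")
  # centroid triangulation reused by every interpolation on this mesh
  # (meshes too small or too degenerate to interpolate from keep NULL)
  mesh$centroid_tri <- if (nrow(centroids) >= 3L)
    tryCatch(interp::tri.mesh(centroids[, 1], centroids[, 2]),
             error = function(e) NULL) else NULL
  mesh
}

triangle_areas <- function(pts, tri) {
  x1 <- pts[tri[, 1], 1]; y1 <- pts[tri[, 1], 2]
  x2 <- pts[tri[, 2], 1]; y2 <- pts[tri[, 2], 2]
  x3 <- pts[tri[, 3], 1]; y3 <- pts[tri[, 3], 2]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

# adjacency by shared edge; ntri x 3 matrix of neighbor indices (NA = none)
triangle_neighbors <- function(tri) {
  ntri <- nrow(tri)
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  owner <- rep(seq_len(ntri), 3L)
  first <- match(key, key)
  nb <- matrix(NA_integer_, ntri, 3)
  dup <- which(first != seq_along(key))           # second owner of an edge
  for (j in dup) {
    i <- owner[j]; k <- owner[first[j]]
    nb[i, which(is.na(nb[i, ]))[1]] <- k
    nb[k, which(is.na(nb[k, ]))[1]] <- i
  }
  nb
}

#' Per-triangle Green-Lagrange strain rates between consecutive frames
#'
#' For each triangle and each pair of consecutive frames, the deformation
#' gradient F is solved exactly from the affine map of the triangle's three
#' vertices, and the Green-Lagrange strain E = (F'F - I)/2 is converted to a
#' rate in percent per second by multiplying with `frame_rate * 100`. E is
#' invariant to rigid motion, so translations and rotations between frames
#' produce zero tensors.
#'
#' @param traj a [feature_trajectories()].
#' @param mesh a [delaunay_triangulate()] mesh on the reference positions.
#' @return An object of class `mesh_strains` with ntri x (T-1) matrices
#'   `exx`, `eyy`, `exy` (%/s), bin `times` (start of each frame pair) and
#'   `frame_rate`. Triangles degenerate in a frame yield `NA` for that pair.
#' @export
compute_green_lagrange_rates <- function(traj, mesh) {
  X <- traj$x; Y <- traj$y
  T_ <- ncol(X)
  if (T_ < 2L) stop("at least two frames are required")
  e <- gl_rates_cpp(X, Y, mesh$triangles, traj$frame_rate * 100, 2e-6)
  structure(list(exx = e$exx, eyy = e$eyy, exy = e$exy,
                 times = (seq_len(T_ - 1L) - 1L) / traj$frame_rate,
                 frame_rate = traj$frame_rate, n_triangles = nrow(e$exx)),
            class = "mesh_strains")
}

#' Laplacian smoothing of per-triangle strains over the mesh
#'
#' Each component is relaxed toward the mean of the values on edge-adjacent
#' triangles: `v <- (1 - weight) * v + weight * mean(neighbors)`, repeated
#' `iterations` times. Undefined (NA) neighbors are excluded from the mean;
#' triangles without defined neighbors are left unchanged.
#'
#' @param strains a `mesh_strains` object.
#' @param mesh the mesh the strains were computed on.
#' @param iterations number of smoothing passes.
#' @param weight relaxation weight in \[0, 1\].
#' @return The smoothed `mesh_strains`.
#' @export
smooth_mesh_strains <- function(strains, mesh, iterations = 1, weight = 0.5) {
  if (iterations < 1) return(strains)
  nb <- mesh$neighbors
  nb[is.na(nb)] <- 0L
  strains$exx <- smooth_mesh_cpp(strains$exx, nb, iterations, weight)
  strains$eyy <- smooth_mesh_cpp(strains$eyy, nb, iterations, weight)
  strains$exy <- smooth_mesh_cpp(strains$exy, nb, iterations, weight)
  strains
}

#' Sliding temporal median (window 3) of per-triangle strains
#'
#' Applies a three-point running median to every triangle and component.
#' Sequence endpoints use the shortened two-point window (the mean of the two
#' values), so no values are fabricated beyond the record.
#'
#' @param strains a `mesh_strains` object with at least 3 time bins.
#' @return The filtered `mesh_strains`.
#' @export
temporal_median_filter <- function(strains) {
  if (ncol(strains$exx) < 3L)
    stop("temporal median filter needs at least 3 time bins")
  strains$exx <- median3_cpp(strains$exx)
  strains$eyy <- median3_cpp(strains$eyy)
  strains$exy <- median3_cpp(strains$exy)
  strains
}

#' Fixed strain-grid geometry
#'
#' The analysis grid covering the image: 90 rows (y) by 120 columns (x) with
#' 10-pixel spacing (1200 x 900 pixels, about 200 um per cell at 1200 dpi).
#' Cell centers are at `x = (col - 0.5) * spacing`,
#' `y = (row - 0.5) * spacing`.
#'
#' @param nrow,ncol,spacing grid dimensions and pixel spacing.
#' @return A list with the grid dimensions and cell-center coordinates.
#' @export
strain_grid_spec <- function(nrow = 90, ncol = 120, spacing = 10) {
  list(nrow = nrow, ncol = ncol, spacing = spacing,
       x = (seq_len(ncol) - 0.5) * spacing,
       y = (seq_len(nrow) - 0.5) * spacing)
}

#' @rdname strain_grid_spec
#' @param row,col grid cell indices.
#' @param gs a grid spec.
#' @export
grid_cell_index <- function(row, col, nrow = 90, ncol = 120) {
  stopifnot(all(row >= 1 & row <= nrow), all(col >= 1 & col <= ncol))
  as.integer(row + (col - 1) * nrow)
}

#' @rdname strain_grid_spec
#' @export
grid_cell_coords <- function(row, col, gs = strain_grid_spec()) {
  c(x = gs$x[col], y = gs$y[row])
}

# barycentric interpolation weights from triangle centroids to points;
# sparse (npts x ntri), zero rows for points outside the centroid hull
centroid_weights <- function(mesh, px, py) {
  ctm <- mesh$centroid_tri
  if (is.null(ctm)) {
    if (nrow(mesh$centroids) < 3L)
      stop("mesh has too few triangles to interpolate from")
    ctm <- interp::tri.mesh(mesh$centroids[, 1], mesh$centroids[, 2])
  }
  loc <- interp::tri.find(ctm, px, py)
  inside <- loc$tr > 0
  idx <- which(inside)
  W <- Matrix::sparseMatrix(
    i = rep(idx, 3L),
    j = c(loc$i1[idx], loc$i2[idx], loc$i3[idx]),
    x = c(loc$bc[idx, 1], loc$bc[idx, 2], loc$bc[idx, 3]),
    dims = c(length(px), nrow(mesh$centroids)))
  list(W = W, inside = inside)
}

apply_weights <- function(W, inside, S) {
  if (anyNA(S)) {
    S0 <- S
    S0[!is.finite(S0)] <- 0
    G <- as.matrix(W %*% S0)
    bad <- as.matrix((abs(W) > 0) %*% is.na(S)) > 0
    G[bad] <- NA
  } else {
    G <- as.matrix(W %*% S)
  }
  G[!inside, ] <- NA
  G
}

#' Interpolate mesh strains onto the fixed strain grid
#'
#' Linear barycentric interpolation of each tensor component from the
#' triangle centroids (reference coordinates) onto the fixed 90 x 120 grid,
#' per time bin. Grid cells outside the contact outline or outside the
#' centroid hull are undefined (`NA`), never zero.
#'
#' @param strains a `mesh_strains` object (typically smoothed and median
#'   filtered).
#' @param mesh the triangle mesh.
#' @param contact optional contact outline: a [contact_geometry()] or a list
#'   with `center` and `radius` (pixels). `NULL` restricts only to the
#'   centroid hull.
#' @param gs grid spec from [strain_grid_spec()].
#' @param weights optional precomputed weights from a previous call on the
#'   same mesh (`attr(grid, "weights")`), to avoid recomputing point location.
#' @return An object of class `strain_grid` with `exx`, `eyy`, `exy` as
#'   (nrow*ncol) x nbins matrices in column-major cell order (cell = row +
#'   (col-1)*nrow), the per-cell `defined` mask, `in_contact` mask, grid
#'   geometry and bin `times`.
#' @export
interpolate_to_grid <- function(strains, mesh, contact = NULL,
                                gs = strain_grid_spec(), weights = NULL) {
  if (is.null(mesh) || nrow(mesh$triangles) == 0L) stop("empty mesh")
  px <- rep(gs$x, each = gs$nrow)
  py <- rep(gs$y, times = gs$ncol)
  if (is.null(weights)) weights <- centroid_weights(mesh, px, py)
  inside <- weights$inside
  if (!is.null(contact)) {
    d2 <- (px - contact$center[1])^2 + (py - contact$center[2])^2
    inside <- inside & d2 <= contact$radius^2
  }
  g <- structure(list(exx = apply_weights(weights$W, inside, strains$exx),
                      eyy = apply_weights(weights$W, inside, strains$eyy),
                      exy = apply_weights(weights$W, inside, strains$exy),
                      defined = inside, in_contact = inside,
                      nrow = gs$nrow, ncol = gs$ncol, spacing = gs$spacing,
                      times = strains$times, frame_rate = strains$frame_rate),
                 class = "strain_grid")
  attr(g, "weights") <- weights
  g
}

#' Interpolate mesh strains at arbitrary pixel locations
#'
#' Same barycentric scheme as [interpolate_to_grid()] but evaluated only at
#' the requested points (used, e.g., to drive simulated afferents from the
#' strain at their receptive-field centers without building the full grid).
#'
#' @param strains,mesh as in [interpolate_to_grid()].
#' @param points n x 2 matrix of pixel coordinates.
#' @return list with npts x nbins matrices `exx`, `eyy`, `exy` (NA outside the
#'   centroid hull) and the bin `times`.
#' @export
interpolate_at_points <- function(strains, mesh, points) {
  points <- matrix(as.numeric(points), ncol = 2)
  w <- centroid_weights(mesh, points[, 1], points[, 2])
  list(exx = apply_weights(w$W, w$inside, strains$exx),
       eyy = apply_weights(w$W, w$inside, strains$eyy),
       exy = apply_weights(w$W, w$inside, strains$exy),
       times = strains$times)
}
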