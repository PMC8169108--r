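test_that("Delaunay triangulation handles the textbook cases", {
  # unit square: 2 triangles sharing a diagonal
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  mesh <- delaunay_triangulate(sq)
  expect_equal(nrow(mesh$triangles), 2)
  # 5x5 regular grid: 2 * 4 * 4 = 32 triangles
  g <- as.matrix(expand.grid(0:4, 0:4))
  mesh <- delaunay_triangulate(g)
  expect_equal(nrow(mesh$triangles), 32)
  # collinear points are rejected with a clear error
  expect_error(delaunay_triangulate(cbind(1:5, 2 * (1:5) + 1)))
})

test_that("triangle adjacency connects exactly the edge-sharing triangles", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  mesh <- delaunay_triangulate(sq)
  nb <- mesh$neighbors
  expect_equal(sort(nb[!is.na(nb)]), c(1L, 2L))  # the two share one edge
})

test_that("identical consecutive frames give exactly zero strain rates", {
  pts <- scatter_points(30, seed = 2)
  traj <- feature_trajectories(x = cbind(pts[, 1], pts[, 1]),
                               y = cbind(pts[, 2], pts[, 2]))
  mesh <- delaunay_triangulate(traj)
  st <- compute_green_lagrange_rates(traj, mesh)
  expect_true(all(st$exx == 0) && all(st$eyy == 0) && all(st$exy == 0))
})

test_that("rigid motions between frames produce zero Green-Lagrange rates", {
  set.seed(9)
  pts <- scatter_points(40, seed = 9)
  for (i in 1:25) {
    A <- random_rotation()
    b <- stats::rnorm(2, sd = 10)
    traj <- two_frame_traj(pts, A, b)
    mesh <- delaunay_triangulate(traj)
    st <- compute_green_lagrange_rates(traj, mesh)
    expect_lt(max(abs(st$exx), abs(st$eyy), abs(st$exy)), 1e-9)
  }
})

test_that("uniform stretch matches the closed-form strain rate", {
  # x -> 1.1 x at 50 Hz: exx = 0.5 (1.1^2 - 1) * 50 * 100 = 525 %/s
  pts <- scatter_points(20, seed = 4)
  traj <- two_frame_traj(pts, diag(c(1.1, 1)))
  mesh <- delaunay_triangulate(traj)
  st <- compute_green_lagrange_rates(traj, mesh)
  expect_equal(max(abs(st$exx - 525)), 0, tolerance = 1e-9)
  expect_lt(max(abs(st$eyy)), 1e-9)
  expect_lt(max(abs(st$exy)), 1e-9)
})

test_that("random affine deformations match the F-based oracle", {
  set.seed(21)
  pts <- scatter_points(35, seed = 21)
  mesh <- delaunay_triangulate(pts)
  for (i in 1:50) {
    A <- diag(2) + matrix(stats::rnorm(4, sd = 0.05), 2, 2)
    traj <- two_frame_traj(pts, A, stats::rnorm(2))
    st <- compute_green_lagrange_rates(traj, mesh)
    expected <- gl_oracle(A)
    expect_equal(as.numeric(st$exx), rep(unname(expected["exx"]), nrow(st$exx)),
                 tolerance = 1e-10)
    expect_equal(as.numeric(st$eyy), rep(unname(expected["eyy"]), nrow(st$eyy)),
                 tolerance = 1e-10)
    expect_equal(as.numeric(st$exy), rep(unname(expected["exy"]), nrow(st$exy)),
                 tolerance = 1e-10)
  }
})

test_that("mesh smoothing leaves constant fields unchanged and averages impulses", {
  pts <- as.matrix(expand.grid(seq(0, 40, 10), seq(0, 40, 10)))
  mesh <- delaunay_triangulate(pts)
  ntri <- nrow(mesh$triangles)
  mk <- function(m) structure(list(exx = m, eyy = m, exy = m,
                                   times = 0, frame_rate = 50),
                              class = "mesh_strains")
  cst <- mk(matrix(3.7, ntri, 4))
  sm <- smooth_mesh_strains(cst, mesh, iterations = 5, weight = 0.8)
  expect_equal(sm$exx, cst$exx)
  # single impulse with weight 1: the impulse triangle takes its neighbors'
  # mean (0); every other triangle is updated from the input values (Jacobi)
  imp <- matrix(0, ntri, 1)
  k <- which(rowSums(!is.na(mesh$neighbors)) == 3)[1]
  imp[k, 1] <- 9
  sm <- smooth_mesh_strains(mk(imp), mesh, iterations = 1, weight = 1)
  expect_equal(sm$exx[k, 1], 0)
  for (j in stats::na.omit(mesh$neighbors[k, ]))
    expect_equal(sm$exx[j, 1],
                 mean(imp[stats::na.omit(mesh$neighbors[j, ]), 1]))
})

test_that("temporal median filter kills impulses and keeps constants", {
  mk <- function(v) structure(list(exx = rbind(v), eyy = rbind(v),
                                   exy = rbind(v), times = seq_along(v),
                                   frame_rate = 50),
                              class = "mesh_strains")
  out <- temporal_median_filter(mk(rep(2, 6)))
  expect_equal(as.numeric(out$exx), rep(2, 6))
  out <- temporal_median_filter(mk(c(0, 9, 0)))
  expect_equal(out$exx[1, 2], 0)
  out <- temporal_median_filter(mk(c(1, 2, 3, 100, 5)))
  expect_equal(out$exx[1, 2:4], c(2, 3, 5))
  expect_error(temporal_median_filter(mk(c(1, 2))), "at least 3")
})

test_that("grid interpolation reproduces linear fields and flags undefined cells", {
  geom <- tiny_geom()
  mesh <- delaunay_triangulate(geom$features)
  ntri <- nrow(mesh$triangles)
  # field linear in (x, y) sampled at centroids
  f <- function(x, y) 0.3 * x - 0.1 * y + 2
  v <- f(mesh$centroids[, 1], mesh$centroids[, 2])
  st <- structure(list(exx = cbind(v), eyy = cbind(v), exy = cbind(v),
                       times = 0, frame_rate = 50),
                  class = "mesh_strains")
  g <- interpolate_to_grid(st, mesh, contact = geom)
  expect_equal(dim(matrix(g$exx[, 1], g$nrow, g$ncol)), c(90, 120))
  gs <- strain_grid_spec()
  xy <- cbind(rep(gs$x, each = 90), rep(gs$y, times = 120))
  def <- which(!is.na(g$exx[, 1]))
  expect_gt(length(def), 10)
  expect_equal(g$exx[def, 1], f(xy[def, 1], xy[def, 2]), tolerance = 1e-10)
  # out-of-contact cells are undefined, never zero
  d2 <- (xy[, 1] - geom$center[1])^2 + (xy[, 2] - geom$center[2])^2
  outside <- d2 > geom$radius^2
  expect_true(all(is.na(g$exx[outside, 1])))
})

test_that("point interpolation agrees with the grid at matching locations", {
  geom <- tiny_geom()
  mesh <- delaunay_triangulate(geom$features)
  v <- mesh$centroids[, 1] * 0.01
  st <- structure(list(exx = cbind(v), eyy = cbind(v), exy = cbind(v),
                       times = 0, frame_rate = 50),
                  class = "mesh_strains")
  g <- interpolate_to_grid(st, mesh, contact = geom)
  cell <- which(!is.na(g$exx[, 1]))[5]
  rc <- c((cell - 1) %% 90 + 1, (cell - 1) %/% 90 + 1)
  pt <- grid_cell_coords(rc[1], rc[2])
  s <- interpolate_at_points(st, mesh, matrix(pt, 1))
  expect_equal(s$exx[1, 1], g$exx[cell, 1], tolerance = 1e-12)
})
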