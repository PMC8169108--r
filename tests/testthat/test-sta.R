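test_that("a spikeless afferent yields an all-undefined STA map", {
  set.seed(1)
  B <- 60
  p <- make_pooled(exx = rnorm(B), eyy = rnorm(B), exy = rnorm(B),
                   counts = rep(0L, B))
  expect_message(map <- compute_sta(p, seed = 3), "no spikes")
  expect_true(all(is.na(map$values)))
  expect_equal(map$n_spike_frames, 0L)
})

test_that("exchanging spike and no-spike selections negates the raw map", {
  set.seed(2)
  B <- 80
  counts <- rep(c(1L, 0L), each = B / 2)
  exx <- matrix(rnorm(3 * B), 3, B)
  p <- make_pooled(exx, exx * 0.5, -exx, counts = counts)
  a <- compute_sta(p, seed = 5, threshold = FALSE)
  p2 <- p
  p2$counts <- cbind(1L - counts)
  b <- compute_sta(p2, seed = 5, threshold = FALSE)
  # equal selection sizes make the no-spike draw exhaustive, so the swap is
  # exact
  expect_equal(a$values, -b$values, tolerance = 1e-12)
})

test_that("the no-spike draw is seeded and bit-reproducible", {
  set.seed(3)
  B <- 200
  counts <- rbinom(B, 1, 0.2)
  p <- make_pooled(matrix(rnorm(5 * B), 5, B), matrix(rnorm(5 * B), 5, B),
                   matrix(rnorm(5 * B), 5, B), counts = counts)
  a <- compute_sta(p, seed = 7)
  b <- compute_sta(p, seed = 7)
  expect_identical(a$values, b$values)
})

test_that("multi-spike bins enter the spike selection with multiplicity", {
  # cell value differs between a 3-spike bin and 1-spike bins; the weighted
  # mean must match direct repetition
  B <- 40
  counts <- rep(0L, B); counts[1] <- 3L; counts[2] <- 1L
  v <- rnorm(B)
  p <- make_pooled(v, v, v, counts = counts)
  map <- compute_sta(p, seed = 1, channel = "exx", threshold = FALSE)
  spike_mean <- (3 * v[1] + v[2]) / 4
  zero_mean_all <- NULL  # the 4 no-spike draws are random; check via seeds
  # reconstruct the same draw
  set.seed(1)
  ns <- sample(which(counts == 0), 4)
  expect_equal(map$values[p$cells[1]], spike_mean - mean(v[ns]),
               tolerance = 1e-12)
})

test_that("fewer zero-spike bins than spike frames falls back with a warning", {
  B <- 20
  counts <- rep(2L, B); counts[1:3] <- 0L
  p <- make_pooled(rnorm(B), rnorm(B), rnorm(B), counts = counts)
  expect_warning(map <- compute_sta(p, seed = 1), "with replacement")
  expect_equal(map$n_spike_frames, sum(counts))
})

test_that("cells below 50% contact persistence are masked", {
  B <- 50
  counts <- rep(c(1L, 0L), length.out = B)
  exx <- matrix(5, 3, B)
  exx[1, seq_len(round(0.7 * B))] <- NA   # 30% persistence -> masked
  exx[2, seq_len(round(0.4 * B))] <- NA   # 60% persistence -> kept
  p <- make_pooled(exx, exx, exx, counts = counts)
  map <- compute_sta(p, seed = 2, threshold = FALSE)
  expect_true(is.na(map$values[p$cells[1]]))
  expect_false(is.na(map$values[p$cells[2]]))
  pm <- contact_persistence_mask(p)
  expect_false(pm$mask[p$cells[1]])
  expect_true(pm$mask[p$cells[2]])
  expect_equal(pm$fraction[p$cells[3]], 1)
})

test_that("sta_peak searches the right region and matches a brute-force scan", {
  B <- 30
  counts <- rep(c(1L, 0L), length.out = B)
  set.seed(9)
  n <- 25
  exx <- matrix(rnorm(n * B), n, B) +
    outer(seq_len(n) / n, counts - 0.5)  # graded spike-locked signal
  cells <- grid_cell_index(rep(45, n), 40 + seq_len(n))
  p <- make_pooled(exx, exx, exx, counts = counts, cells = cells)
  map <- compute_sta(p, seed = 4, threshold = FALSE)
  rf <- receptive_field(center = c(600, 445), radius = 150,
                        relation_to_contact = "inside")
  pk <- sta_peak(map, rf)
  # brute-force: max defined value within the disk
  xy <- cbind(rep(strain_grid_spec()$x, each = 90),
              rep(strain_grid_spec()$y, times = 120))
  inside <- (xy[, 1] - 600)^2 + (xy[, 2] - 445)^2 <= 150^2
  v <- as.vector(map$values); v[!inside] <- NA
  expect_equal(pk$peak_value, max(v, na.rm = TRUE))
  best_cell <- which(v == max(v, na.rm = TRUE))[1]
  expect_equal(unname(pk$peak_cell["row"]), (best_cell - 1) %% 90 + 1)
  expect_equal(unname(pk$peak_cell["col"]), (best_cell - 1) %/% 90 + 1)
  # all-undefined map -> undefined stats
  p0 <- p; p0$counts <- cbind(rep(0L, B))
  suppressMessages(map0 <- compute_sta(p0, seed = 1))
  pk0 <- sta_peak(map0, rf)
  expect_true(is.na(pk0$peak_value))
})

test_that("a single defined cell is its own peak", {
  B <- 30
  counts <- rep(c(1L, 0L), length.out = B)
  v <- ifelse(counts == 1, 7, 0)  # mean difference exactly 7
  p <- make_pooled(v, v * 0, v * 0, counts = counts,
                   cells = grid_cell_index(45, 60))
  map <- compute_sta(p, seed = 2, channel = "exx", threshold = FALSE)
  rf <- receptive_field(grid_cell_coords(45, 60), 150, "inside")
  pk <- sta_peak(map, rf)
  expect_equal(pk$peak_value, 7)
  expect_equal(unname(pk$peak_cell), c(45, 60))
})
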