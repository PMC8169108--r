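test_that("predictor construction obeys the rectification identities", {
  set.seed(4)
  tens <- matrix(rnorm(90), ncol = 3)
  X <- build_predictors(tens, set = "full6")
  expect_equal(ncol(X), 6)
  expect_true(all(X >= 0))
  expect_equal(X[, "exx_pos"] - X[, "exx_neg"], tens[, 1])
  expect_equal(X[, "eyy_pos"] - X[, "eyy_neg"], tens[, 2])
  expect_equal(X[, "exy_pos"] - X[, "exy_neg"], tens[, 3])
  # the norm predictor ignores the rotation argument
  a <- build_predictors(tens, rotation = 0, set = "norm")
  b <- build_predictors(tens, rotation = 37, set = "norm")
  expect_equal(a, b, tolerance = 1e-12)
  # e1/e2 predictors match the brute-force angle scan
  e1 <- build_predictors(tens, set = "e1")
  e2 <- build_predictors(tens, set = "e2")
  for (i in seq_len(nrow(tens))) {
    o <- principal_oracle(tens[i, 1], tens[i, 2], tens[i, 3])
    expect_lt(abs(e1[i, 1] - (-o$e1)), 1e-5)
    expect_lt(abs(e2[i, 1] - o$e2), 1e-5)
  }
})

test_that("a noiseless in-class rate is recovered exactly by the CV fit", {
  set.seed(5)
  n <- 400
  tens <- matrix(rnorm(3 * n), ncol = 3)
  X <- build_predictors(tens, set = "full6")
  y <- 3 * X[, "exx_neg"] + 5
  folds <- rep(c("a", "b"), length.out = n)
  fit <- fit_linear_cv(X, y, folds)
  expect_equal(fit$pooled_r2, 1, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["exx_neg"]), 3, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 5, tolerance = 1e-6)
})

test_that("predictor-independent responses give near-zero pooled R2", {
  r2 <- sapply(1:20, function(s) {
    set.seed(s)
    n <- 500
    X <- build_predictors(matrix(rnorm(3 * n), ncol = 3), set = "full6")
    y <- rnorm(n)
    fit_linear_cv(X, y, rep(c("a", "b"), length.out = n))$pooled_r2
  })
  expect_true(all(r2 <= 0.05))
})

test_that("degenerate responses and designs are guarded", {
  set.seed(6)
  n <- 100
  X <- build_predictors(matrix(rnorm(3 * n), ncol = 3), set = "full6")
  expect_warning(fit <- fit_linear_cv(X, rep(4, n),
                                      rep(c("a", "b"), length.out = n)),
                 "zero variance")
  expect_equal(fit$pooled_r2, 0)
  # duplicated column -> collinear drop with warning, fit still works
  X2 <- cbind(X, dup = X[, 1])
  y <- X[, 1] + rnorm(n, sd = 0.1)
  expect_warning(fit <- fit_linear_cv(X2, y, rep(c("a", "b"), length.out = n)),
                 "collinear")
  expect_gt(fit$pooled_r2, 0.5)
  # empty fold errors
  expect_error(fit_linear_cv(X, y, rep("a", n)), "two populated folds")
})

test_that("cross-validation never predicts from the training fold", {
  # a fold-specific mean shift: training on the other fold cannot see it,
  # so held-out predictions must miss it; an (illegal) refit on all data
  # would not
  set.seed(7)
  n <- 200
  X <- build_predictors(matrix(rnorm(3 * n), ncol = 3), set = "full6")
  folds <- rep(c("a", "b"), each = n / 2)
  y <- as.numeric(folds == "a") * 10 + rnorm(n, sd = 0.01)
  fit <- fit_linear_cv(X, y, folds)
  expect_lt(fit$pooled_r2, 0)   # out-of-fold predictions are anti-informative
  # and shuffling the fold labels changes the predictions
  set.seed(8)
  fit2 <- fit_linear_cv(X, y, sample(folds))
  expect_false(isTRUE(all.equal(fit$predictions, fit2$predictions)))
})

test_that("best_location takes the defined maximum with lexicographic ties", {
  map <- matrix(NA_real_, 90, 120)
  rf <- receptive_field(grid_cell_coords(45, 60), 150, "inside")
  map[45, 60] <- 0.4
  expect_equal(as.numeric(best_location(map, rf)), c(45, 60))
  # tie: two equal maxima -> smallest (row, col)
  map[44, 61] <- 0.9
  map[46, 59] <- 0.9
  expect_equal(as.numeric(best_location(map, rf)), c(44, 61))
  # matches an exhaustive scan
  set.seed(9)
  map2 <- matrix(runif(90 * 120), 90, 120)
  bl <- best_location(map2, rf)
  xy <- full_grid_xy()
  inside <- (xy[, 1] - grid_cell_coords(45, 60)[1])^2 +
    (xy[, 2] - grid_cell_coords(45, 60)[2])^2 <= 150^2
  v <- as.vector(map2); v[!inside] <- NA
  expect_equal(map2[bl["row"], bl["col"]], max(v, na.rm = TRUE))
  # no defined cell -> error
  expect_error(best_location(matrix(NA_real_, 90, 120), rf), "no defined")
})

test_that("the rotation scan recovers a noiseless preferred orientation", {
  set.seed(10)
  B <- 600
  tens <- matrix(rnorm(3 * B, sd = 50), ncol = 3)
  theta_star <- 30
  e_par <- rotate_tensor(tens, theta_star)[, 1]
  rate <- 2 * pmax(-e_par, 0)
  p <- make_pooled(tens[, 1], tens[, 2], tens[, 3], counts = rep(0L, B),
                   rates = rate, cells = grid_cell_index(45, 60))
  rs <- rotation_scan(p, unit = 1, location = c(45, 60))
  expect_equal(rs$best_orientation, theta_star)
  expect_equal(max(rs$r2_compressive), 1, tolerance = 1e-6)
  expect_equal(length(rs$angles), 19)
  # an isotropic (norm-driven) response is flat across rotations
  p$rates <- cbind(strain_norm(tens))
  rs2 <- rotation_scan(p, unit = 1, location = c(45, 60))
  expect_lt(diff(range(rs2$r2_compressive)), 0.1)
})

test_that("direction tuning picks the maximal direction with fixed-order ties", {
  tab <- data.frame(direction = rep(c("ulnar", "distal", "radial",
                                      "proximal"), each = 4),
                    mean_rate = rep(c(10, 20, 5, 1), each = 4))
  dt <- direction_tuning(tab)
  expect_equal(dt$preferred, "distal")
  expect_equal(unname(dt$relative["N"]), 20)
  # scaling all rates leaves the preferred direction unchanged
  tab2 <- tab; tab2$mean_rate <- tab2$mean_rate * 3.7
  expect_equal(direction_tuning(tab2)$preferred, "distal")
  # all equal -> first of the fixed order, with a warning
  tab$mean_rate <- 2
  expect_warning(dt <- direction_tuning(tab), "tie")
  expect_equal(dt$preferred, "ulnar")
})

test_that("rate comparisons build matched pairs and friction ratios", {
  tab <- expand.grid(direction = c("ulnar", "distal", "radial", "proximal"),
                     friction = c("high", "low"),
                     movement = c("forward", "backward"),
                     repetition = 1:2, stringsAsFactors = FALSE)
  tab$mean_rate <- ifelse(tab$friction == "low", 8, 10)
  rc <- rate_comparisons(tab)
  expect_equal(rc$ratio_mean, 0.8, tolerance = 1e-12)
  expect_equal(rc$ratio_sd, 0, tolerance = 1e-12)
  expect_equal(nrow(rc$friction), 8)       # 4 directions x 2 movements
  expect_equal(nrow(rc$forward_backward), 8)
  # identical rates -> ratio 1 and forward equals backward
  tab$mean_rate <- 6
  rc <- rate_comparisons(tab)
  expect_equal(rc$ratio_mean, 1)
  expect_equal(rc$forward_backward$mean_rate_forward,
               rc$forward_backward$mean_rate_backward)
})

test_that("rate-force correlations behave for proportional and constant rates", {
  cfg <- trial_config("ulnar", "high", seed = 3)
  f <- simulate_force_traces(slip_wave_params(1.0), cfg)
  mv <- segment_movements(f)
  w <- c(mv$forward[1], mv$backward[2])
  # a rate proportional to the tangential force component along the movement
  t50 <- seq(0, max(f$time), by = 0.02)
  fx50 <- stats::approx(f$time, f$tangential_x, xout = t50)$y
  rate <- structure(list(rate = 3 * fx50, times = t50, frame_rate = 50),
                    class = "smoothed_rate")
  # the constant normal force is flagged as zero-variance
  suppressWarnings(r <- rate_force_correlation(rate, f, w))
  expect_equal(unname(r["tangential_x"]), 1.0, tolerance = 1e-6)
  expect_true(is.na(r["normal"]))
  # constant rate -> undefined correlation, flagged
  rate$rate <- rep(2, length(t50))
  suppressWarnings(expect_warning(
    r <- rate_force_correlation(rate, f, w), "zero-variance"))
  expect_true(is.na(r["tangential_x"]))
})
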