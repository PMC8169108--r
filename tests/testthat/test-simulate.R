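test_that("zero tangential movement produces a perfectly static stimulus", {
  geom <- tiny_geom()
  cfg <- trial_config("ulnar", "high", forward_amplitude = 0,
                      backward_amplitude = 0, seed = 1)
  traj <- simulate_feature_trajectories(geom, slip_wave_params(1.0), cfg)
  expect_true(all(traj$x == traj$x[, 1]))
  mesh <- delaunay_triangulate(traj)
  st <- compute_green_lagrange_rates(traj, mesh)
  expect_true(all(st$exx == 0) && all(st$eyy == 0) && all(st$exy == 0))
})

test_that("lower friction reaches full slip strictly earlier", {
  geom <- tiny_geom()
  for (dir in c("ulnar", "distal", "radial", "proximal")) {
    cfg <- trial_config(dir, "high", seed = 3)
    t_high <- attr(simulate_feature_trajectories(
      geom, slip_wave_params(1.0), cfg), "true_full_slip_times")
    t_low <- attr(simulate_feature_trajectories(
      geom, slip_wave_params(0.5), cfg), "true_full_slip_times")
    expect_lt(t_low["forward"], t_high["forward"])
    expect_lt(t_low["backward"], t_high["backward"])
  }
})

test_that("strain rates vanish before movement onset and after full slip", {
  geom <- tiny_geom()
  cfg <- trial_config("distal", "high", seed = 5)
  traj <- simulate_feature_trajectories(geom, slip_wave_params(1.0), cfg)
  mesh <- delaunay_triangulate(traj)
  st <- compute_green_lagrange_rates(traj, mesh)
  tl <- attr(traj, "timeline")
  fs <- attr(traj, "true_full_slip_times")
  pre <- st$times < tl$t_fwd_start - 1 / cfg$frame_rate
  post_fwd <- st$times > fs["forward"] & st$times < tl$t_fwd_end - 0.02
  post_bwd <- st$times > fs["backward"] & st$times < tl$t_bwd_end - 0.02
  mx <- function(sel) max(abs(st$exx[, sel]), abs(st$eyy[, sel]),
                          abs(st$exy[, sel]))
  expect_lt(mx(pre), 1e-9)
  expect_lt(mx(post_fwd), 1e-9)
  expect_lt(mx(post_bwd), 1e-9)
})

test_that("degenerate geometry is rejected with a clear diagnostic", {
  expect_error(contact_geometry(radius = -3), "positive")
  expect_error(contact_geometry(radius = 5, feature_spacing = 24), "fewer than 3")
})

test_that("force plateau follows mu * F_n and the frictionless limit is zero", {
  cfg <- trial_config("ulnar", "high", seed = 2)
  f <- simulate_force_traces(slip_wave_params(1.0), cfg)
  mag <- sqrt(f$tangential_x^2 + f$tangential_y^2)
  tl <- attr(f, "timeline")
  plateau <- f$time > attr(f, "true_full_slip_times")["forward"] + 0.1 &
    f$time < tl$t_fwd_end - 0.05
  expect_equal(mean(mag[plateau]), 4.0, tolerance = 1e-6)
  f0 <- simulate_force_traces(slip_wave_params(0), cfg)
  expect_true(all(f0$tangential_x == 0) && all(f0$tangential_y == 0))
  expect_equal(unname(attr(f0, "true_full_slip_times")["forward"]),
               tl$t_fwd_start)
})

test_that("force plateau onset matches the trajectory full-slip time within one frame", {
  geom <- tiny_geom()
  for (mu in c(0.5, 1.0)) {
    cfg <- trial_config("radial", if (mu == 1) "high" else "low", seed = 4)
    wave <- slip_wave_params(mu)
    traj <- simulate_feature_trajectories(geom, wave, cfg)
    f <- simulate_force_traces(wave, cfg)
    mag <- sqrt(f$tangential_x^2 + f$tangential_y^2)
    # first time the trace reaches 99.9% of its plateau value
    t99 <- f$time[which(mag >= 0.999 * mu * cfg$normal_force)[1]]
    expect_lt(abs(t99 - attr(traj, "true_full_slip_times")["forward"]), 0.02)
  }
})

test_that("baseline-only afferents are Poisson at the requested rate", {
  cfg <- trial_config("ulnar", "high", seed = 10)
  tens <- matrix(0, 100, 3)
  b <- 20
  truth <- afferent_ground_truth(baseline_rate = b)
  counts <- sapply(1:100, function(s) {
    cfg$seed <- s
    simulate_afferent_spikes(tens, truth, cfg, duration = 2)$n
  })
  # expected b*T = 40 per run; total across 100 runs within the central
  # 99% Poisson interval
  total <- sum(counts)
  expect_gt(total, stats::qpois(0.005, 100 * b * 2))
  expect_lt(total, stats::qpois(0.995, 100 * b * 2))
  # zero baseline, zero gains: empty train
  cfg$seed <- 1
  expect_equal(simulate_afferent_spikes(
    tens, afferent_ground_truth(), cfg, duration = 2)$n, 0)
})

test_that("compression-driven spikes land where the compressive drive is", {
  cfg <- trial_config("ulnar", "high", seed = 1)
  n <- 200
  tens <- matrix(0, n, 3)
  tens[81:100, 1] <- -150          # compressive pulse, frames 81-100
  attr(tens, "times") <- (seq_len(n) - 1) / 50
  truth <- afferent_ground_truth(gain_compressive = 1.0)
  ok <- sapply(1:20, function(s) {
    cfg$seed <- s
    spk <- simulate_afferent_spikes(tens, truth, cfg, duration = 4)
    length(spk$times) > 0 &&
      mean(spk$times >= 80 / 50 & spk$times < 100 / 50) >= 0.8
  })
  expect_gte(mean(ok), 0.95)
})

test_that("the full factorial design is generated deterministically", {
  geom <- tiny_geom()
  truths <- list(afferent_ground_truth(rf_center = c(45, 60),
                                       gain_compressive = 0.6,
                                       baseline_rate = 1))
  ds1 <- generate_dataset(truths, master_seed = 11, geom = geom,
                          repetitions = 1, cache_strains = FALSE)
  expect_equal(length(ds1$trials), 8)
  tab <- table(ds1$design$direction, ds1$design$friction)
  expect_true(all(tab == 1))
  ds2 <- generate_dataset(truths, master_seed = 11, geom = geom,
                          repetitions = 1, cache_strains = FALSE)
  expect_identical(serialize(ds1, NULL), serialize(ds2, NULL))
  ds3 <- generate_dataset(truths, master_seed = 12, geom = geom,
                          repetitions = 1, cache_strains = FALSE)
  sp1 <- unlist(lapply(ds1$trials, function(tr) tr$spikes[[1]]$times))
  sp3 <- unlist(lapply(ds3$trials, function(tr) tr$spikes[[1]]$times))
  expect_false(identical(sp1, sp3))
})

test_that("the default design has 40 trials, 5 per direction-friction cell", {
  # design table only; trials themselves are exercised elsewhere
  design <- expand.grid(repetition = 1:5,
                        direction = c("ulnar", "distal", "radial", "proximal"),
                        friction = c("high", "low"))
  expect_equal(nrow(design), 40)
  expect_true(all(table(design$direction, design$friction) == 5))
})
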