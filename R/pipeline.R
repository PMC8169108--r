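#' Default pipeline configuration
#'
#' All tunable parameters of the simulate - strain - phases - STA - encode -
#' report pipeline, with their defaults. The configuration round-trips
#' losslessly through JSON (and YAML if available).
#'
#' @param master_seed master RNG seed.
#' @param out_dir output directory of the run.
#' @return A named list of parameters.
#' @export
default_config <- function(master_seed = 1L, out_dir = "slipstrain_run") {
  list(
    master_seed = as.integer(master_seed),
    out_dir = out_dir,
    stages = list(simulate = TRUE, strain = TRUE, phases = TRUE, sta = TRUE,
                  encode = TRUE, report = TRUE),
    geometry = list(center = c(600, 450), radius = 300, feature_spacing = 24),
    wave = list(mu_high = 1.0, mu_low = 0.5, full_slip_displacement = 3.0,
                slip_onset_profile_exponent = 1.0, lateral_contraction = 0.2),
    repetitions = 5L,
    noise_sd = 0.005,
    truths = list(list(rf_center = c(50, 75), rf_radius = 150,
                       preferred_orientation = 0, gain_compressive = 0.8,
                       gain_tensile = 0, gain_shear = 0, baseline_rate = 0.5,
                       label = "FA-like")),
    smoothing = list(iterations = 1, weight = 0.5),
    phases = list(epsilon = 0.05, sustain = 0.05, cutoff_hz = 10),
    sta = list(channel = "norm", deviation = "sem"),
    encoding = list(scheme = "friction2", angles = seq(0, 90, by = 5))
  )
}

config_truths <- function(cfg) {
  lapply(cfg$truths, function(tr) do.call(afferent_ground_truth, tr))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (simulate, strain+phases pooling,
#' STA, encoding, report), writing all artifacts plus a manifest (config,
#' seeds, package version, per-stage timing) to the output directory. A
#' rerun with an identical configuration reproduces identical numeric
#' artifacts.
#'
#' @param config a configuration list from [default_config()] (or a path to
#'   a JSON/YAML file of one).
#' @return Invisibly, the output directory path; the run artifacts live
#'   there.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  st <- config$stages
  if ((isTRUE(st$sta) || isTRUE(st$encode)) && !isTRUE(st$strain))
    stop("configuration error: the STA and encoding stages require the ",
         "strain stage")
  if (isTRUE(st$strain) && !isTRUE(st$simulate))
    stop("configuration error: the strain stage requires the simulate stage")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config,
                   package_version = as.character(utils::packageVersion("slipstrain")),
                   timings = list())
  tic <- function() proc.time()[["elapsed"]]

  dataset <- pooled <- NULL
  if (isTRUE(st$simulate)) {
    t0 <- tic()
    geom <- do.call(contact_geometry, config$geometry)
    dataset <- generate_dataset(
      truths = config_truths(config), master_seed = config$master_seed,
      geom = geom,
      wave_high = slip_wave_params(config$wave$mu_high,
                                   config$wave$full_slip_displacement,
                                   config$wave$slip_onset_profile_exponent,
                                   config$wave$lateral_contraction),
      wave_low = slip_wave_params(config$wave$mu_low,
                                  config$wave$full_slip_displacement,
                                  config$wave$slip_onset_profile_exponent,
                                  config$wave$lateral_contraction),
      repetitions = config$repetitions, noise_sd = config$noise_sd)
    write_spike_csv(dataset, file.path(out, "spikes.csv"))
    manifest$timings$simulate <- tic() - t0
  }
  phase_rows <- NULL
  if (isTRUE(st$strain)) {
    t0 <- tic()
    pooled <- pool_partial_slip(dataset,
                                smoothing_iterations = config$smoothing$iterations,
                                smoothing_weight = config$smoothing$weight)
    manifest$timings$strain <- tic() - t0
  }
  if (isTRUE(st$phases)) {
    t0 <- tic()
    phase_rows <- do.call(rbind, lapply(seq_along(dataset$trials), function(i) {
      ph <- trial_phases(dataset$trials[[i]],
                         epsilon = config$phases$epsilon,
                         sustain = config$phases$sustain,
                         cutoff_hz = config$phases$cutoff_hz)
      do.call(rbind, lapply(ph, function(p)
        data.frame(trial = i, movement = p$movement,
                   t_onset = p$onset[1], t_partial = p$partial_slip[1],
                   t_full_slip = p$full_slip_time, t_end = p$window[2])))
    }))
    utils::write.csv(phase_rows, file.path(out, "phases.csv"),
                     row.names = FALSE)
    manifest$timings$phases <- tic() - t0
  }
  results <- list()
  if (isTRUE(st$sta)) {
    t0 <- tic()
    gs <- strain_grid_spec()
    results$sta <- lapply(seq_along(dataset$truths), function(a) {
      truth <- dataset$truths[[a]]
      map <- compute_sta(pooled, unit = a, channel = config$sta$channel,
                         seed = config$master_seed,
                         deviation = config$sta$deviation)
      rf <- truth_receptive_field(truth, dataset$geometry, gs)
      pk <- sta_peak(map, rf, gs)
      list(map = map, peak = pk, unit = a)
    })
    pk <- do.call(rbind, lapply(results$sta, function(s)
      data.frame(unit = s$unit, peak = s$peak$peak_value,
                 row = s$peak$peak_cell[1], col = s$peak$peak_cell[2],
                 n_spike_frames = s$map$n_spike_frames)))
    utils::write.csv(pk, file.path(out, "sta_peaks.csv"), row.names = FALSE)
    manifest$timings$sta <- tic() - t0
  }
  if (isTRUE(st$encode)) {
    t0 <- tic()
    gs <- strain_grid_spec()
    results$encoding <- lapply(seq_along(dataset$truths), function(a) {
      truth <- dataset$truths[[a]]
      rf <- truth_receptive_field(truth, dataset$geometry, gs)
      map <- r2_map(pooled, unit = a, scheme = config$encoding$scheme)
      loc <- tryCatch(best_location(map, rf, contact = pooled$contact, gs = gs),
                      error = function(e) NULL)
      scan <- if (!is.null(loc))
        rotation_scan(pooled, unit = a, location = loc,
                      scheme = config$encoding$scheme,
                      angles = config$encoding$angles) else NULL
      tab <- partial_rate_table(dataset, unit = a)
      list(unit = a, r2_map = map, best_location = loc,
           best_r2 = if (is.null(loc)) NA_real_ else attr(loc, "r2"),
           rotation = scan, tuning = direction_tuning(tab),
           comparisons = rate_comparisons(tab))
    })
    enc <- do.call(rbind, lapply(results$encoding, function(e)
      data.frame(unit = e$unit, best_r2 = e$best_r2,
                 best_row = if (is.null(e$best_location)) NA else e$best_location[1],
                 best_col = if (is.null(e$best_location)) NA else e$best_location[2],
                 best_orientation = if (is.null(e$rotation)) NA else
                   e$rotation$best_orientation,
                 preferred_direction = e$tuning$preferred,
                 friction_ratio_mean = e$comparisons$ratio_mean)))
    utils::write.csv(enc, file.path(out, "encoding_summary.csv"),
                     row.names = FALSE)
    manifest$timings$encode <- tic() - t0
  }
  if (isTRUE(st$report)) {
    t0 <- tic()
    render_report(out, results = results, dataset = dataset, pooled = pooled)
    manifest$timings$report <- tic() - t0
  }
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

# receptive field of a ground-truth unit, in pixel coordinates, classified
# against the contact outline
truth_receptive_field <- function(truth, geom, gs = strain_grid_spec()) {
  ctr <- grid_cell_coords(truth$rf_center[1], truth$rf_center[2], gs)
  d <- sqrt(sum((ctr - geom$center)^2))
  rel <- if (d <= geom$radius - truth$rf_radius) "inside"
         else if (d <= geom$radius + truth$rf_radius) "border"
         else "outside"
  receptive_field(ctr, radius = truth$rf_radius, relation_to_contact = rel)
}

#' Render figures and a machine-readable summary for a pipeline run
#'
#' Writes PNG figures (STA heatmap with contact and receptive-field
#' contours, R-squared map, rotation-scan curves, direction tuning) and a
#' JSON summary of the headline quantities. Units without spikes render as
#' an explicit "no data" panel.
#'
#' @param out_dir run directory.
#' @param results,dataset,pooled internal results from [run_pipeline()];
#'   when omitted the function reports whatever artifacts it finds.
#' @return Invisibly, the summary list.
#' @export
render_report <- function(out_dir, results = NULL, dataset = NULL,
                          pooled = NULL) {
  summary <- list()
  if (!is.null(results$sta)) {
    for (s in results$sta) {
      png_path <- file.path(out_dir, sprintf("sta_unit%d.png", s$unit))
      grDevices::png(png_path, width = 700, height = 520)
      plot_sta_map(s$map, dataset, s$unit)
      grDevices::dev.off()
      summary[[sprintf("unit%d_sta_peak", s$unit)]] <- s$peak$peak_value
    }
  }
  if (!is.null(results$encoding)) {
    for (e in results$encoding) {
      png_path <- file.path(out_dir, sprintf("r2_map_unit%d.png", e$unit))
      grDevices::png(png_path, width = 700, height = 520)
      plot_value_map(e$r2_map, main = sprintf("Cross-validated R2, unit %d",
                                              e$unit))
      grDevices::dev.off()
      if (!is.null(e$rotation)) {
        png_path <- file.path(out_dir, sprintf("rotation_unit%d.png", e$unit))
        grDevices::png(png_path, width = 600, height = 450)
        plot(e$rotation$angles, e$rotation$r2_compressive, type = "b",
             col = "red", xlab = "reference-frame rotation (deg)",
             ylab = expression(R^2),
             ylim = range(c(e$rotation$r2_compressive, e$rotation$r2_tensile),
                          finite = TRUE),
             main = sprintf("Rotation scan, unit %d", e$unit))
        graphics::lines(e$rotation$angles, e$rotation$r2_tensile, type = "b",
                        col = "blue")
        graphics::legend("topright", legend = c("compressive", "tensile"),
                         col = c("red", "blue"), lty = 1, bty = "n")
        grDevices::dev.off()
      }
      summary[[sprintf("unit%d_best_r2", e$unit)]] <- e$best_r2
      summary[[sprintf("unit%d_best_orientation", e$unit)]] <-
        if (is.null(e$rotation)) NA else e$rotation$best_orientation
      summary[[sprintf("unit%d_preferred_direction", e$unit)]] <-
        e$tuning$preferred
      summary[[sprintf("unit%d_friction_ratio", e$unit)]] <-
        e$comparisons$ratio_mean
    }
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

plot_value_map <- function(map, main = "", col_low = "red") {
  if (all(is.na(map))) {
    graphics::plot.new()
    graphics::title(main = paste(main, "- no data"))
    return(invisible())
  }
  # rows span y: display with y increasing upward, x rightward
  graphics::image(x = seq_len(ncol(map)) * 10 - 5,
                  y = seq_len(nrow(map)) * 10 - 5,
                  z = t(map), xlab = "x (px, ulnar right)", ylab = "y (px)",
                  main = main, useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE))
}

plot_sta_map <- function(map, dataset = NULL, unit = NULL) {
  plot_value_map(map$values, main = sprintf(
    "STA (%s), %d spike frames", map$channel, map$n_spike_frames))
  if (!is.null(dataset)) {
    geom <- dataset$geometry
    th <- seq(0, 2 * pi, length.out = 180)
    graphics::lines(geom$center[1] + geom$radius * cos(th),
                    geom$center[2] + geom$radius * sin(th), col = "grey40")
    if (!is.null(unit)) {
      truth <- dataset$truths[[unit]]
      ctr <- grid_cell_coords(truth$rf_center[1], truth$rf_center[2])
      graphics::lines(ctr[1] + truth$rf_radius * cos(th),
                      ctr[2] + truth$rf_radius * sin(th), col = "black")
    }
  }
}
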