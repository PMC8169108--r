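#' Read a pipeline configuration file
#'
#' JSON is always supported; YAML is used when the yaml package is
#' installed. Missing entries are filled from [default_config()].
#'
#' @param path configuration file path (.json, .yml or .yaml).
#' @return A configuration list.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configurations")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  }
  utils::modifyList(default_config(), cfg)
}

#' Export all spike times of a dataset as CSV
#'
#' @param dataset a `slip_dataset`.
#' @param path output CSV path.
#' @return Invisibly, the written data.frame (trial, unit, t_seconds).
#' @export
write_spike_csv <- function(dataset, path) {
  rows <- list()
  for (i in seq_along(dataset$trials)) {
    for (a in seq_along(dataset$trials[[i]]$spikes)) {
      st <- dataset$trials[[i]]$spikes[[a]]$times
      if (length(st))
        rows[[length(rows) + 1L]] <- data.frame(trial = i, unit = a,
                                                t_seconds = st)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(trial = integer(), unit = integer(),
                        t_seconds = numeric())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Export the force traces of a dataset as CSV
#'
#' @param dataset a `slip_dataset`.
#' @param path output CSV path.
#' @param trials which trials to export (default: all).
#' @return Invisibly, the written data.frame.
#' @export
write_force_csv <- function(dataset, path, trials = seq_along(dataset$trials)) {
  rows <- lapply(trials, function(i) {
    f <- dataset$trials[[i]]$forces
    data.frame(trial = i, time = f$time, normal = f$normal,
               tangential_x = f$tangential_x, tangential_y = f$tangential_y,
               plate_x = f$plate_x, plate_y = f$plate_y)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write a dataset (and optionally strain grids) to an HDF5 file
#'
#' Requires the rhdf5 package. Layout: `/trials/<id>/{features_x, features_y,
#' forces, spikes_unit<k>}`, `/truth/unit<k>`, plus a JSON sidecar
#' (`<path>.json`) with the full configuration.
#'
#' @param dataset a `slip_dataset`.
#' @param path output .h5 path.
#' @return Invisibly, `path`.
#' @export
write_dataset_h5 <- function(dataset, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("the rhdf5 package is required for HDF5 export")
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "trials")
  for (i in seq_along(dataset$trials)) {
    g <- sprintf("trials/trial%03d", i)
    rhdf5::h5createGroup(path, g)
    tr <- dataset$trials[[i]]
    rhdf5::h5write(tr$trajectories$x, path, paste0(g, "/features_x"))
    rhdf5::h5write(tr$trajectories$y, path, paste0(g, "/features_y"))
    rhdf5::h5write(cbind(time = tr$forces$time, normal = tr$forces$normal,
                         tangential_x = tr$forces$tangential_x,
                         tangential_y = tr$forces$tangential_y),
                   path, paste0(g, "/forces"))
    for (a in seq_along(tr$spikes))
      rhdf5::h5write(tr$spikes[[a]]$times, path,
                     sprintf("%s/spikes_unit%d", g, a))
    rhdf5::h5write(unlist(tr$config[c("tangential_speed", "forward_amplitude",
                                      "backward_amplitude", "normal_force")]),
                   path, paste0(g, "/meta_numeric"))
  }
  rhdf5::h5createGroup(path, "truth")
  for (a in seq_along(dataset$truths)) {
    tr <- dataset$truths[[a]]
    rhdf5::h5write(c(tr$rf_center, tr$rf_radius, tr$preferred_orientation,
                     tr$gain_compressive, tr$gain_tensile, tr$gain_shear,
                     tr$baseline_rate),
                   path, sprintf("truth/unit%d", a))
  }
  rhdf5::h5closeAll()
  jsonlite::write_json(
    list(master_seed = dataset$master_seed,
         design = dataset$design,
         geometry = dataset$geometry[c("center", "radius", "pixel_pitch",
                                       "feature_spacing")]),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
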