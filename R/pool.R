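#' Pool partial-slip strain bins, spike counts and firing rates of a dataset
#'
#' Runs the full strain pipeline (Green-Lagrange rates, mesh smoothing,
#' temporal median, grid interpolation) for every trial of a dataset, keeps
#' only the 20 ms bins inside the partial-slip phase of each movement
#' (segmented from the force traces), and pools them across all conditions
#' and repetitions, as the spike-triggered and encoding analyses require.
#' Only grid cells inside the contact outline are retained; trials are
#' processed one at a time so the full grids are never all held in memory.
#'
#' @param dataset a `slip_dataset` from [generate_dataset()].
#' @param smoothing_iterations,smoothing_weight mesh smoothing parameters.
#' @param gs grid spec, see [strain_grid_spec()].
#' @param phases optional precomputed list of [trial_phases()] per trial.
#' @param cells optional integer vector of grid cell indices to pool; the
#'   default pools every cell inside the contact outline. Restricting to the
#'   few cells an analysis needs (e.g. one location for a rotation scan)
#'   skips most of the interpolation work.
#' @return An object of class `pooled_bins`:
#'   `cells` (indices into the 90 x 120 grid of retained cells), `cell_xy`
#'   (their pixel coordinates), `exx`/`eyy`/`exy` (ncells x B pooled
#'   matrices), `counts` (B x n_units spike counts per bin), `rates`
#'   (B x n_units Gaussian-smoothed firing rates at the bin frames), `bins`
#'   (data.frame with trial, movement, friction, direction, repetition,
#'   time), `persistence` (per retained cell, fraction of pooled bins in
#'   contact), and the grid geometry.
#' @export
pool_partial_slip <- function(dataset, smoothing_iterations = 1,
                              smoothing_weight = 0.5,
                              gs = strain_grid_spec(), phases = NULL,
                              cells = NULL) {
  geom <- dataset$geometry
  mesh <- dataset$mesh
  n_units <- length(dataset$truths)

  px <- rep(gs$x, each = gs$nrow)
  py <- rep(gs$y, times = gs$ncol)
  if (is.null(cells)) {
    in_contact <- (px - geom$center[1])^2 + (py - geom$center[2])^2 <=
      geom$radius^2
    cells <- which(in_contact)
  }
  w_all <- centroid_weights(mesh, px[cells], py[cells])

  comp <- list(exx = list(), eyy = list(), exy = list())
  counts <- list(); rates <- list(); bins <- list()
  for (i in seq_along(dataset$trials)) {
    trial <- dataset$trials[[i]]
    cfg <- trial$config
    ph <- if (is.null(phases)) trial_phases(trial) else phases[[i]]

    strains <- if (!is.null(trial$mesh_strains) &&
                   smoothing_iterations == 1 && smoothing_weight == 0.5) {
      trial$mesh_strains
    } else {
      temporal_median_filter(smooth_mesh_strains(
        compute_green_lagrange_rates(trial$trajectories, mesh), mesh,
        iterations = smoothing_iterations, weight = smoothing_weight))
    }

    sel <- lapply(ph, function(p) partial_slip_bins(p, strains$times))
    keep <- c(sel$forward, sel$backward)
    if (length(keep) == 0L) next
    mv <- rep(c("forward", "backward"), c(length(sel$forward),
                                          length(sel$backward)))

    comp$exx[[length(comp$exx) + 1L]] <-
      apply_weights(w_all$W, w_all$inside, strains$exx[, keep, drop = FALSE])
    comp$eyy[[length(comp$eyy) + 1L]] <-
      apply_weights(w_all$W, w_all$inside, strains$eyy[, keep, drop = FALSE])
    comp$exy[[length(comp$exy) + 1L]] <-
      apply_weights(w_all$W, w_all$inside, strains$exy[, keep, drop = FALSE])

    dur <- attr(trial$trajectories, "timeline")$duration
    cnt <- matrix(0L, length(keep), n_units)
    rt <- matrix(0, length(keep), n_units)
    for (a in seq_len(n_units)) {
      cnt[, a] <- bin_spikes(trial$spikes[[a]],
                             bin_times = strains$times)[keep]
      sr <- smoothed_rate(trial$spikes[[a]], duration = dur,
                          frame_rate = cfg$frame_rate)
      rt[, a] <- sr$rate[keep]
    }
    counts[[length(counts) + 1L]] <- cnt
    rates[[length(rates) + 1L]] <- rt
    bins[[length(bins) + 1L]] <- data.frame(
      trial = i, movement = mv, friction = cfg$friction,
      direction = cfg$direction, repetition = cfg$repetition,
      time = strains$times[keep], stringsAsFactors = FALSE)
  }
  if (length(bins) == 0L) stop("no partial-slip bins found in the dataset")

  exx <- do.call(cbind, comp$exx)
  eyy <- do.call(cbind, comp$eyy)
  exy <- do.call(cbind, comp$exy)
  structure(list(cells = cells, cell_xy = cbind(x = px[cells], y = py[cells]),
                 exx = exx, eyy = eyy, exy = exy,
                 counts = do.call(rbind, counts),
                 rates = do.call(rbind, rates),
                 bins = do.call(rbind, bins),
                 persistence = rowMeans(is.finite(exx)),
                 nrow = gs$nrow, ncol = gs$ncol, spacing = gs$spacing,
                 contact = list(center = geom$center, radius = geom$radius),
                 n_units = n_units),
            class = "pooled_bins")
}

# fold factor for a cross-validation scheme
cv_folds <- function(bins, scheme = c("friction2", "movement2", "direction4")) {
  scheme <- match.arg(scheme)
  switch(scheme,
         friction2 = factor(bins$friction),
         movement2 = factor(bins$movement),
         direction4 = factor(bins$direction,
                             levels = c("ulnar", "distal", "radial",
                                        "proximal")))
}

# pixel coordinates of every cell of the full grid, column-major
full_grid_xy <- function(gs = strain_grid_spec()) {
  cbind(x = rep(gs$x, each = gs$nrow), y = rep(gs$y, times = gs$ncol))
}
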