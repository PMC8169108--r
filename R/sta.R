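#' Spike-triggered average strain map
#'
#' For one afferent, the pooled partial-slip bins are split into a spike
#' selection (bins with at least one spike, a bin with n spikes entering n
#' times) and an equal-sized no-spike selection drawn at random (seeded,
#' without replacement when possible) from the zero-spike bins. The STA is
#' the per-cell mean of the chosen scalar strain channel over the spike
#' selection minus the mean over the no-spike selection. Cells whose |STA|
#' does not exceed `4 * (deviation(spike) + deviation(no-spike))` are set to
#' `NA`, as are cells that were not inside the contact area for at least half
#' of the pooled partial-slip time.
#'
#' The deviation is by default the standard error of each selection's mean
#' (`sd/sqrt(n)`); the literal standard deviation is available with
#' `deviation = "sd"`.
#'
#' @param pooled a [pool_partial_slip()] result.
#' @param unit index of the afferent within the pooled dataset.
#' @param channel scalar channel: "norm", "e1", "e2", or a raw component.
#' @param seed RNG seed for the no-spike draw.
#' @param deviation "sem" (default) or "sd".
#' @param threshold apply the deviation threshold (disable to inspect the raw
#'   difference map).
#' @param persistence_min minimum in-contact fraction for a cell to be kept.
#' @return An object of class `sta_map`: `values` (90 x 120 matrix, `NA`
#'   where undefined), `n_spike_frames`, `channel`, `persistence` (90 x 120),
#'   `in_contact` (logical 90 x 120) and the selections' sizes.
#' @export
compute_sta <- function(pooled, unit = 1L, channel = "norm", seed = 1L,
                        deviation = c("sem", "sd"), threshold = TRUE,
                        persistence_min = 0.5) {
  deviation <- match.arg(deviation)
  counts <- pooled$counts[, unit]
  M <- pooled_channel(pooled, channel)
  B <- ncol(M)

  full <- function(v) {
    out <- matrix(NA_real_, pooled$nrow, pooled$ncol)
    out[pooled$cells] <- v
    out
  }
  in_contact <- matrix(FALSE, pooled$nrow, pooled$ncol)
  in_contact[pooled$cells] <- TRUE
  persistence <- full(pooled$persistence)

  spike_idx <- which(counts > 0)
  n_spk <- sum(counts[spike_idx])
  if (n_spk == 0L) {
    message("no spikes in the partial-slip bins; STA is undefined everywhere")
    return(structure(list(values = full(NA_real_), n_spike_frames = 0L,
                          channel = channel, persistence = persistence,
                          in_contact = in_contact, n_no_spike = 0L),
                     class = "sta_map"))
  }
  zero_idx <- which(counts == 0)
  set.seed(seed)
  if (length(zero_idx) >= n_spk) {
    ns_idx <- zero_idx[sample.int(length(zero_idx), n_spk, replace = FALSE)]
  } else {
    warning("fewer zero-spike bins (", length(zero_idx), ") than spike ",
            "frames (", n_spk, "); sampling with replacement")
    ns_idx <- zero_idx[sample.int(length(zero_idx), n_spk, replace = TRUE)]
  }

  w <- counts[spike_idx]
  # weighted first/second moments per cell, NA-aware
  moments_w <- function(X, w) {
    ok <- is.finite(X)
    Xw <- X; Xw[!ok] <- 0
    n <- as.numeric(ok %*% w)
    m <- as.numeric(Xw %*% w) / n
    m[n == 0] <- NA
    m2 <- as.numeric(Xw^2 %*% w) / n
    v <- (m2 - m^2) * n / pmax(n - 1, 1)
    list(mean = m, n = n, sd = sqrt(pmax(v, 0)))
  }
  ms <- moments_w(M[, spike_idx, drop = FALSE], w)
  mn <- moments_w(M[, ns_idx, drop = FALSE], rep(1, length(ns_idx)))
  sta <- ms$mean - mn$mean

  if (threshold) {
    dev <- if (deviation == "sem")
      ms$sd / sqrt(pmax(ms$n, 1)) + mn$sd / sqrt(pmax(mn$n, 1))
    else ms$sd + mn$sd
    sta[abs(sta) < 4 * dev] <- NA
  }
  sta[pooled$persistence < persistence_min] <- NA

  structure(list(values = full(sta), n_spike_frames = n_spk,
                 channel = channel, persistence = persistence,
                 in_contact = in_contact, n_no_spike = length(ns_idx),
                 deviation = deviation),
            class = "sta_map")
}

# scalar channel over the pooled cells
pooled_channel <- function(pooled, channel) {
  switch(channel,
         exx = pooled$exx, eyy = pooled$eyy, exy = pooled$exy,
         norm = sqrt(pooled$exx^2 + pooled$eyy^2 + 2 * pooled$exy^2),
         e1 = (pooled$exx + pooled$eyy) / 2 -
           sqrt(((pooled$exx - pooled$eyy) / 2)^2 + pooled$exy^2),
         e2 = (pooled$exx + pooled$eyy) / 2 +
           sqrt(((pooled$exx - pooled$eyy) / 2)^2 + pooled$exy^2),
         stop("unknown channel: ", channel))
}

#' Peak of an STA map
#'
#' For units inside or on the border of the contact area the maximum defined
#' STA value is searched within the receptive-field disk; for units outside
#' the contact it is searched anywhere inside the contact area. An
#' all-undefined search region yields undefined (NA) statistics.
#'
#' @param map an [compute_sta()] result.
#' @param rf a [receptive_field()] (pixel center, radius, relation to
#'   contact).
#' @param gs grid spec matching the map.
#' @return An object of class `sta_stats`: `peak_value`, `peak_cell`
#'   (`c(row, col)`) and `search_region`.
#' @export
sta_peak <- function(map, rf, gs = strain_grid_spec()) {
  xy <- full_grid_xy(gs)
  if (rf$relation_to_contact %in% c("inside", "border")) {
    region <- (xy[, 1] - rf$center[1])^2 + (xy[, 2] - rf$center[2])^2 <=
      rf$radius^2
    region_label <- "receptive field"
  } else {
    region <- as.vector(map$in_contact)
    region_label <- "whole contact"
  }
  v <- as.vector(map$values)
  v[!region] <- NA
  if (all(is.na(v)))
    return(structure(list(peak_value = NA_real_, peak_cell = c(NA, NA),
                          search_region = region_label),
                     class = "sta_stats"))
  best <- max(v, na.rm = TRUE)
  cand <- which(v == best)
  rc <- cbind(row = (cand - 1L) %% map_nrow(map) + 1L,
              col = (cand - 1L) %/% map_nrow(map) + 1L)
  rc <- rc[order(rc[, 1], rc[, 2]), , drop = FALSE]
  structure(list(peak_value = best, peak_cell = rc[1, ],
                 search_region = region_label),
            class = "sta_stats")
}

map_nrow <- function(map) nrow(map$values)

#' Per-cell contact persistence over the partial-slip bins
#'
#' @param pooled a [pool_partial_slip()] result.
#' @param threshold minimum in-contact fraction for a cell to be kept.
#' @return list with `fraction` and logical `mask` (90 x 120 matrices; cells
#'   never covered by the grid interpolation are NA in `fraction` and FALSE
#'   in `mask`).
#' @export
contact_persistence_mask <- function(pooled, threshold = 0.5) {
  fraction <- matrix(NA_real_, pooled$nrow, pooled$ncol)
  fraction[pooled$cells] <- pooled$persistence
  mask <- !is.na(fraction) & fraction >= threshold
  list(fraction = fraction, mask = mask)
}
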