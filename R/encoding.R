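#' Build nonnegative strain predictors at one grid location
#'
#' Extracts the strain-rate tensor series at a grid cell, rotates it by
#' `rotation` degrees, and assembles the predictor columns of the requested
#' model family. All columns are nonnegative; the full model uses the six
#' half-wave rectified components (stretch and compression of both axial
#' components, positive and negative shear).
#'
#' @param pooled a [pool_partial_slip()] result, or directly an n x 3 tensor
#'   matrix (exx, eyy, exy).
#' @param location grid cell `c(row, col)` (ignored when `pooled` is already
#'   a tensor matrix).
#' @param rotation reference-frame rotation in degrees.
#' @param set one of "full6", "norm", "e1", "e2", or "rotated_single".
#' @param component for `rotated_single`: "exx" or "eyy".
#' @param sign for `rotated_single`: "neg" (compression) or "pos" (stretch).
#' @param min_defined minimum fraction of bins in which the location must be
#'   defined.
#' @return A numeric matrix of predictors (rows = bins; `NA` rows mark bins
#'   where the location was undefined, to be dropped pairwise with the
#'   response).
#' @export
build_predictors <- function(pooled, location = NULL, rotation = 0,
                             set = c("full6", "norm", "e1", "e2",
                                     "rotated_single"),
                             component = c("exx", "eyy"),
                             sign = c("neg", "pos"), min_defined = 0.5) {
  set <- match.arg(set)
  tens <- extract_tensor(pooled, location, min_defined)
  if (rotation != 0) tens <- rotate_tensor(tens, rotation)
  switch(set,
         full6 = rectify_components(tens),
         norm = cbind(norm = strain_norm(tens)),
         e1 = cbind(e1 = -principal_strains(tens)$e1),
         e2 = cbind(e2 = principal_strains(tens)$e2),
         rotated_single = {
           component <- match.arg(component)
           sign <- match.arg(sign)
           v <- if (component == "exx") tens[, 1] else tens[, 2]
           v <- if (sign == "neg") pmax(-v, 0) else pmax(v, 0)
           cbind(v)
         })
}

extract_tensor <- function(pooled, location, min_defined = 0.5) {
  if (inherits(pooled, "pooled_bins")) {
    if (is.null(location)) stop("a grid location is required")
    cell <- grid_cell_index(location[1], location[2], pooled$nrow,
                            pooled$ncol)
    k <- match(cell, pooled$cells)
    if (is.na(k)) stop("location is outside the contact area")
    tens <- cbind(pooled$exx[k, ], pooled$eyy[k, ], pooled$exy[k, ])
    if (mean(stats::complete.cases(tens)) < min_defined)
      stop("location undefined in more than ", (1 - min_defined) * 100,
           "% of the partial-slip bins")
    tens
  } else {
    as_tensor_matrix(pooled)
  }
}

#' Cross-validated linear encoding model
#'
#' Ordinary least squares with an intercept, fitted on the data excluding one
#' fold and used to predict that fold; held-out predictions from all folds
#' are pooled and summarized by a single
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)` over the pooled
#' predictions (which can be negative). Rank-deficient designs drop the
#' aliased columns with a warning. Rows with undefined predictors are dropped
#' pairwise with the response.
#'
#' @param X predictor matrix (rows = bins).
#' @param y response (firing rate, spikes/s).
#' @param folds factor of fold labels, one per row (e.g. from the friction,
#'   movement, or direction of each bin).
#' @return An object of class `encoding_fit`: `coefficients` (full-data fit,
#'   intercept first), `fold_coefficients`, `pooled_r2`, `predictions`
#'   (held-out, NA for dropped rows), `scheme_levels` and `n`.
#' @export
fit_linear_cv <- function(X, y, folds) {
  X <- as.matrix(X)
  folds <- as.factor(folds)
  if (length(y) != nrow(X) || length(folds) != nrow(X))
    stop("X, y and folds must have matching lengths")
  ok <- stats::complete.cases(X) & is.finite(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]; folds <- droplevels(folds[ok])
  if (nlevels(folds) < 2L) stop("at least two populated folds are required")

  Xi <- cbind(`(Intercept)` = 1, X)
  n_dropped <- 0L
  fit_fold <- function(train) {
    f <- stats::lm.fit(Xi[train, , drop = FALSE], y[train])
    cf <- f$coefficients
    if (anyNA(cf)) {
      n_dropped <<- max(n_dropped, sum(is.na(cf)))
      cf[is.na(cf)] <- 0
    }
    cf
  }
  pred <- rep(NA_real_, length(y))
  fold_cf <- list()
  for (lev in levels(folds)) {
    test <- folds == lev
    if (!any(test) || all(test)) stop("empty training or test fold: ", lev)
    cf <- fit_fold(!test)
    fold_cf[[lev]] <- cf
    pred[test] <- Xi[test, , drop = FALSE] %*% cf
  }
  if (n_dropped > 0L)
    warning("rank-deficient design; dropping ", n_dropped,
            " collinear column(s)")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    warning("response has zero variance; R^2 set to 0")
    r2 <- 0
  } else {
    r2 <- 1 - sum((y - pred)^2) / sst
  }
  cf_all <- suppressWarnings(fit_fold(rep(TRUE, length(y))))
  structure(list(coefficients = cf_all, fold_coefficients = fold_cf,
                 pooled_r2 = r2, predictions = pred,
                 scheme_levels = levels(folds), n = length(y)),
            class = "encoding_fit")
}

#' Map of cross-validated R-squared over the strain grid
#'
#' Fits the six-predictor rectified model at every grid cell that stayed in
#' contact for at least half of the pooled partial-slip time, and stores the
#' pooled cross-validated R-squared. Cells outside the mask, or where a fit
#' fails, are `NA` (never 0).
#'
#' @param pooled a [pool_partial_slip()] result.
#' @param unit afferent index.
#' @param scheme cross-validation scheme: "friction2", "movement2" or
#'   "direction4".
#' @param persistence_min minimal in-contact fraction per cell.
#' @return A 90 x 120 matrix of pooled R-squared values with attribute
#'   `scheme`.
#' @export
r2_map <- function(pooled, unit = 1L, scheme = "friction2",
                   persistence_min = 0.5) {
  folds <- cv_folds(pooled$bins, scheme)
  y <- pooled$rates[, unit]
  out <- matrix(NA_real_, pooled$nrow, pooled$ncol)
  lev <- levels(folds)
  test_sets <- lapply(lev, function(l) which(folds == l))
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    warning("response has zero variance; R^2 map is all NA")
    return(structure(out, scheme = scheme))
  }
  keep <- which(pooled$persistence >= persistence_min)
  train_sets <- lapply(test_sets, function(ts) setdiff(seq_along(y), ts))
  for (k in keep) {
    tens <- cbind(pooled$exx[k, ], pooled$eyy[k, ], pooled$exy[k, ])
    has_na <- anyNA(tens)
    okr <- if (has_na) stats::complete.cases(tens) else
      rep(TRUE, nrow(tens))
    if (has_na && mean(okr) < persistence_min) next
    X <- cbind(1, pmax(tens[, 1], 0), pmax(-tens[, 1], 0),
               pmax(tens[, 2], 0), pmax(-tens[, 2], 0),
               pmax(tens[, 3], 0), pmax(-tens[, 3], 0))
    pred <- rep(NA_real_, length(y))
    bad <- FALSE
    for (j in seq_along(test_sets)) {
      tr <- train_sets[[j]]; ts <- test_sets[[j]]
      if (has_na) { tr <- tr[okr[tr]]; ts <- ts[okr[ts]] }
      if (length(tr) <= ncol(X) || length(ts) == 0L) { bad <- TRUE; break }
      f <- .lm.fit(X[tr, , drop = FALSE], y[tr])
      cf <- numeric(ncol(X))
      cf[f$pivot] <- f$coefficients                # rank-deficient -> 0
      pred[ts] <- X[ts, , drop = FALSE] %*% cf
    }
    if (bad) next
    use <- okr & is.finite(pred)
    out[pooled$cells[k]] <- 1 - sum((y[use] - pred[use])^2) /
      sum((y[use] - mean(y[use]))^2)
  }
  structure(out, scheme = scheme)
}

#' Best-performing grid location for an afferent
#'
#' The defined cell with maximal R-squared within the receptive field (units
#' inside or on the border of the contact) or within the whole contact area
#' (units outside). Ties are broken toward the smallest `(row, col)`.
#'
#' @param map a [r2_map()] result (90 x 120 matrix).
#' @param rf a [receptive_field()].
#' @param contact contact outline (`center`, `radius`) used for units outside
#'   the contact.
#' @param gs grid spec.
#' @return `c(row, col)` of the selected cell, with attribute `r2`.
#' @export
best_location <- function(map, rf, contact = NULL, gs = strain_grid_spec()) {
  xy <- full_grid_xy(gs)
  if (rf$relation_to_contact %in% c("inside", "border")) {
    region <- (xy[, 1] - rf$center[1])^2 + (xy[, 2] - rf$center[2])^2 <=
      rf$radius^2
  } else {
    if (is.null(contact)) stop("contact outline needed for an outside unit")
    region <- (xy[, 1] - contact$center[1])^2 +
      (xy[, 2] - contact$center[2])^2 <= contact$radius^2
  }
  v <- as.vector(map)
  v[!region] <- NA
  if (all(is.na(v))) stop("no defined R^2 value in the search region")
  best <- max(v, na.rm = TRUE)
  cand <- which(v == best)
  rc <- cbind(row = (cand - 1L) %% nrow(map) + 1L,
              col = (cand - 1L) %/% nrow(map) + 1L)
  rc <- rc[order(rc[, 1], rc[, 2]), , drop = FALSE]
  structure(c(row = unname(rc[1, 1]), col = unname(rc[1, 2])), r2 = best)
}

#' Reference-frame rotation scan for preferred strain orientation
#'
#' At a fixed grid location, single-predictor models (with intercept) are
#' fitted for reference-frame rotations of 0 to 90 degrees in 5-degree steps:
#' the half-wave rectified compression and stretch of both rotated axial
#' components (shear is not part of the scan). The compressive and tensile
#' curves reported are those of the rotated x-axis component; the preferred
#' orientation maximizes their sum.
#'
#' @param pooled a [pool_partial_slip()] result.
#' @param unit afferent index.
#' @param location grid cell `c(row, col)` (typically [best_location()]).
#' @param scheme cross-validation scheme.
#' @param angles rotation angles in degrees.
#' @return An object of class `rotation_scan_result` with `angles`,
#'   `r2_compressive` and `r2_tensile` (x-axis component curves),
#'   `r2_compressive_y`/`r2_tensile_y` (y-axis component curves), and
#'   `best_orientation`.
#' @export
rotation_scan <- function(pooled, unit = 1L, location, scheme = "friction2",
                          angles = seq(0, 90, by = 5)) {
  folds <- cv_folds(pooled$bins, scheme)
  y <- pooled$rates[, unit]
  tens <- extract_tensor(pooled, location)
  r2_of <- function(x) fit_linear_cv(cbind(x), y, folds)$pooled_r2
  n <- length(angles)
  cx <- tx <- cy <- ty <- numeric(n)
  for (i in seq_len(n)) {
    rot <- rotate_tensor(tens, angles[i])
    cx[i] <- r2_of(pmax(-rot[, 1], 0))
    tx[i] <- r2_of(pmax(rot[, 1], 0))
    cy[i] <- r2_of(pmax(-rot[, 2], 0))
    ty[i] <- r2_of(pmax(rot[, 2], 0))
  }
  structure(list(angles = angles, r2_compressive = cx, r2_tensile = tx,
                 r2_compressive_y = cy, r2_tensile_y = ty,
                 best_orientation = angles[which.max(cx + tx)],
                 location = location, scheme = scheme),
            class = "rotation_scan_result")
}

#' Mean partial-slip firing rate per trial and movement
#'
#' @param dataset a `slip_dataset`.
#' @param unit afferent index.
#' @param phases optional precomputed [trial_phases()] list.
#' @return data.frame with one row per trial x movement: direction, friction,
#'   repetition, movement and the mean Gaussian-smoothed firing rate over the
#'   partial-slip window.
#' @export
partial_rate_table <- function(dataset, unit = 1L, phases = NULL) {
  rows <- list()
  for (i in seq_along(dataset$trials)) {
    trial <- dataset$trials[[i]]
    ph <- if (is.null(phases)) trial_phases(trial) else phases[[i]]
    dur <- attr(trial$trajectories, "timeline")$duration
    sr <- smoothed_rate(trial$spikes[[unit]], duration = dur)
    for (mv in c("forward", "backward")) {
      w <- ph[[mv]]$partial_slip
      sel <- sr$times >= w[1] & sr$times < w[2]
      rows[[length(rows) + 1L]] <- data.frame(
        trial = i, direction = trial$config$direction,
        friction = trial$config$friction,
        repetition = trial$config$repetition, movement = mv,
        mean_rate = if (any(sel)) mean(sr$rate[sel]) else 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Direction tuning and preferred global direction
#'
#' Mean partial-slip firing rate per plate movement direction, averaged
#' across repetitions, movements (forward/backward) and frictions. The
#' preferred global direction attains the maximal mean rate; ties go to the
#' first of (ulnar, distal, radial, proximal) with a warning. Rates are also
#' reported relative to the preferred direction ("North"), going clockwise
#' N, E, S, W.
#'
#' @param rate_table a [partial_rate_table()] data.frame.
#' @return An object of class `direction_tuning`: `mean_rates` (named by
#'   direction), `preferred`, and `relative` (named N/E/S/W).
#' @export
direction_tuning <- function(rate_table) {
  dirs <- c("ulnar", "distal", "radial", "proximal")
  mr <- vapply(dirs, function(d)
    mean(rate_table$mean_rate[rate_table$direction == d]), numeric(1))
  mx <- max(mr)
  cand <- which(mr == mx)
  if (length(cand) > 1L)
    warning("tie for preferred direction; taking the first of the fixed ",
            "order (ulnar, distal, radial, proximal)")
  pref <- dirs[cand[1]]
  # circular order of the four directions (90 degree steps)
  shift <- (seq_along(dirs) - cand[1]) %% 4
  relative <- mr[order(shift)]
  names(relative) <- c("N", "E", "S", "W")
  structure(list(mean_rates = mr, preferred = pref, relative = relative),
            class = "direction_tuning")
}

#' Paired rate comparisons across movements and frictions
#'
#' Builds the paired per-condition mean rates (averaged across repetitions):
#' forward versus backward (one pair per direction x friction) and low versus
#' high friction (one pair per direction x movement), together with the
#' low/high rate ratio summarized as mean and standard deviation. Pairs with
#' a zero high-friction mean yield an undefined (NA) ratio.
#'
#' @param rate_table a [partial_rate_table()] data.frame.
#' @return list with `forward_backward` and `friction` data.frames, the
#'   per-pair `ratios`, `ratio_mean`, `ratio_sd` and `ratio_median` (the
#'   median is robust to pairs in which the afferent was nearly silent,
#'   where the ratio of two small means is unstable).
#' @export
rate_comparisons <- function(rate_table) {
  agg <- stats::aggregate(mean_rate ~ direction + friction + movement,
                          data = rate_table, FUN = mean)
  fb <- merge(agg[agg$movement == "forward",
                  c("direction", "friction", "mean_rate")],
              agg[agg$movement == "backward",
                  c("direction", "friction", "mean_rate")],
              by = c("direction", "friction"),
              suffixes = c("_forward", "_backward"))
  fr <- merge(agg[agg$friction == "low", c("direction", "movement",
                                           "mean_rate")],
              agg[agg$friction == "high", c("direction", "movement",
                                            "mean_rate")],
              by = c("direction", "movement"), suffixes = c("_low", "_high"))
  if (nrow(fb) == 0L || nrow(fr) == 0L) stop("no matched condition pairs")
  ratios <- ifelse(fr$mean_rate_high > 0,
                   fr$mean_rate_low / fr$mean_rate_high, NA_real_)
  list(forward_backward = fb, friction = fr, ratios = ratios,
       ratio_mean = mean(ratios, na.rm = TRUE),
       ratio_sd = stats::sd(ratios, na.rm = TRUE),
       ratio_median = stats::median(ratios, na.rm = TRUE))
}

#' Correlation of the firing rate with the force components
#'
#' The 1 kHz force components (normal, tangential x and y) and their central
#' difference derivatives are low-pass filtered and resampled to the 50 Hz
#' rate time base over a window covering the tangential loading (all three
#' phases); Pearson correlations with the smoothed firing rate are returned.
#' Zero-variance series yield NA with a warning.
#'
#' @param rate a [smoothed_rate()].
#' @param trace a `force_trace`.
#' @param window `c(start, end)` in seconds (e.g. the movement window).
#' @return Named numeric vector of correlations: normal, tangential_x,
#'   tangential_y and their `_deriv` counterparts.
#' @export
rate_force_correlation <- function(rate, trace, window) {
  sel50 <- rate$times >= window[1] & rate$times <= window[2]
  t50 <- rate$times[sel50]
  y <- rate$rate[sel50]
  comps <- list(normal = trace$normal, tangential_x = trace$tangential_x,
                tangential_y = trace$tangential_y)
  dt <- 1 / trace$signal_rate
  out <- c()
  for (nm in names(comps)) {
    f <- comps[[nm]]
    d <- c(0, (f[-1] - f[-length(f)]) / dt)
    for (variant in c("", "_deriv")) {
      v <- if (variant == "") f else d
      v50 <- stats::approx(trace$time, v, xout = t50)$y
      if (stats::sd(v50) == 0 || stats::sd(y) == 0) {
        warning("zero-variance series; correlation with ", nm, variant,
                " undefined")
        out[paste0(nm, variant)] <- NA_real_
      } else {
        out[paste0(nm, variant)] <- stats::cor(y, v50)
      }
    }
  }
  out
}
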