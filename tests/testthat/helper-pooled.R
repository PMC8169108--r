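# Hand-built pooled_bins fixtures (bypassing the simulator) for fast unit
# tests of the STA and encoding layers.

make_bins <- function(B) {
  data.frame(trial = rep(1:4, length.out = B),
             movement = rep(c("forward", "backward"), length.out = B),
             friction = rep(rep(c("high", "low"), each = 2), length.out = B),
             direction = rep(c("ulnar", "distal", "radial", "proximal"),
                             length.out = B),
             repetition = 1L,
             time = seq_len(B) * 0.02,
             stringsAsFactors = FALSE)
}

# pooled object over arbitrary cells; exx/eyy/exy are ncells x B
make_pooled <- function(exx, eyy, exy, counts, rates = NULL,
                        cells = NULL, persistence = NULL) {
  exx <- rbind(exx); eyy <- rbind(eyy); exy <- rbind(exy)
  B <- ncol(exx)
  n <- nrow(exx)
  if (is.null(cells)) cells <- grid_cell_index(rep(45, n), 50 + seq_len(n))
  gs <- strain_grid_spec()
  xy <- cbind(x = gs$x[(cells - 1L) %/% 90 + 1L],
              y = gs$y[(cells - 1L) %% 90 + 1L])
  if (is.null(persistence)) persistence <- rowMeans(is.finite(exx))
  structure(list(cells = cells, cell_xy = xy, exx = exx, eyy = eyy,
                 exy = exy, counts = cbind(as.integer(counts)),
                 rates = cbind(if (is.null(rates)) numeric(B) else rates),
                 bins = make_bins(B), persistence = persistence,
                 nrow = 90, ncol = 120, spacing = 10,
                 contact = list(center = c(600, 450), radius = 300),
                 n_units = 1L),
            class = "pooled_bins")
}
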