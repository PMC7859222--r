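# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately share no code with the implementation.

# stack-based flood fill labeling; the oracle for label_components()
flood_fill_label <- function(mask, connectivity = 8) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8)
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
          c(1, -1), c(1, 0), c(1, 1))
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!m[i, j] || lab[i, j] > 0) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    lab[i, j] <- cur
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        r <- p[1] + nb[k, 1]; c <- p[2] + nb[k, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
              m[r, c] && lab[r, c] == 0) {
          lab[r, c] <- cur
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# brute-force per-object co-localization: explicit pixel-set intersection
# of every labeled object with a mask
oracle_object_coloc <- function(labels, other_mask, min_overlap = 1) {
  n <- max(labels)
  vapply(seq_len(n), function(l) {
    px <- which(labels == l)
    length(intersect(px, which(other_mask))) >= min_overlap
  }, logical(1))
}

# small, fast simulation parameter set used where physical realism is not
# the point of the test
tiny_params <- function(...) {
  args <- list(
    field_size_px = c(192, 192), n_z = 3, pixel_size_nm = 160,
    n_cells = 2, cell_radius_um = c(5, 6), nucleus_radius_um = c(1.8, 2.4),
    mve_per_cell_mean = 8, guide_spots_per_cell_mean = 8,
    passenger_spots_per_cell_mean = 4, seed = 11L)
  do.call(simulation_params, utils::modifyList(args, list(...)))
}

# disk mask helper for constructed segmentation fixtures
disk <- function(nr, nc, cr, cc, rad) {
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (r - cr)^2 + (c - cc)^2 <= rad^2
}
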