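# Generator: geometry, puncta placement, rendering, determinism and
# statistical control of the truth tables.

test_that("parameter validation rejects impossible settings", {
  expect_error(simulation_params(coloc_fraction_guide = 1.2), "fractions")
  expect_error(simulation_params(nucleus_radius_um = c(6, 9),
                                 cell_radius_um = c(8, 10)),
               "nucleus radius")
  expect_error(simulation_params(n_z = 0))
  expect_error(simulation_params(spot_amplitude = c(nucleus = -1)),
               "named|non-negative")
})

test_that("cell geometry: empty case, disjointness, nuclei containment", {
  p0 <- tiny_params()
  p0$n_cells <- 0L
  g0 <- generate_cell_geometry(p0)
  expect_equal(max(g0$cell_labels), 0)
  expect_equal(nrow(g0$cells), 0)

  p <- tiny_params()
  g <- generate_cell_geometry(p)
  expect_equal(sort(unique(g$cell_labels[g$cell_labels > 0])), 1:2)
  expect_equal(nrow(g$cells), 2)
  # every nucleus pixel lies inside the same cell label
  nuc <- g$nucleus_labels > 0
  expect_true(all(g$cell_labels[nuc] == g$nucleus_labels[nuc]))
  # cells fully inside the field
  expect_false(any(g$cells$border_touching))
})

test_that("cell geometry is deterministic and reports packing failure", {
  p <- tiny_params()
  g1 <- generate_cell_geometry(p)
  g2 <- generate_cell_geometry(p)
  expect_identical(g1$cell_labels, g2$cell_labels)
  expect_identical(g1$nucleus_labels, g2$nucleus_labels)

  crowded <- tiny_params()
  crowded$n_cells <- 30L
  expect_error(generate_cell_geometry(crowded, max_attempts = 20L),
               "placed \\d+ of 30")
})

test_that("puncta placement honours co-localization fractions", {
  p <- tiny_params(coloc_fraction_guide = 1, nuclear_fraction_guide = 0)
  g <- generate_cell_geometry(p)
  s <- place_puncta(g, p)
  guide <- s[s$channel_role == "mirna_guide", ]
  expect_gt(nrow(guide), 0)
  expect_true(all(guide$coloc_flag))
  expect_true(all(!is.na(guide$mve_id)))

  p0 <- tiny_params(coloc_fraction_guide = 0)
  s0 <- place_puncta(generate_cell_geometry(p0), p0)
  g0 <- s0[s0$channel_role == "mirna_guide", ]
  expect_true(all(!g0$coloc_flag))
  # brute-force nearest-MVE distance check: chance proximity stays low
  mve <- s0[s0$channel_role == "mve", ]
  lim <- p0$mve_diameter_nm / 4 / p0$pixel_size_nm
  near <- vapply(seq_len(nrow(g0)), function(i) {
    m <- mve[mve$cell_id == g0$cell_id[i], ]
    if (nrow(m) == 0) return(FALSE)
    min(sqrt((m$r_px - g0$r_px[i])^2 + (m$c_px - g0$c_px[i])^2)) < lim
  }, logical(1))
  expect_lt(mean(near), 0.1)
})

test_that("no guide spots are emitted when their mean is zero", {
  p <- tiny_params(guide_spots_per_cell_mean = 0)
  s <- place_puncta(generate_cell_geometry(p), p)
  expect_equal(sum(s$channel_role == "mirna_guide"), 0)
})

test_that("nuclear fraction places guide spots in the nucleus, uncolocalized", {
  p <- tiny_params(nuclear_fraction_guide = 1, coloc_fraction_guide = 0.5)
  g <- generate_cell_geometry(p)
  s <- place_puncta(g, p)
  guide <- s[s$channel_role == "mirna_guide", ]
  expect_true(all(!guide$coloc_flag))
  idx <- cbind(round(guide$r_px), round(guide$c_px))
  expect_true(all(g$nucleus_labels[idx] == guide$cell_id))
})

test_that("rendering: zero amplitudes give a zero stack; spots are centered", {
  p <- tiny_params(background_level = 0, spot_amplitude = 0,
                   read_noise_sd = 0)
  f <- simulate_field(p)
  expect_true(all(f$stack$data == 0))

  # single noise-free spot: intensity-weighted centroid within 0.1 px
  p1 <- tiny_params(shot_noise = FALSE, read_noise_sd = 0,
                    background_level = 0)
  g <- generate_cell_geometry(p1)
  sp <- data.frame(channel_role = "mve", r_px = 96.3, c_px = 80.7, z = 2L,
                   cell_id = 1L, mve_id = 1L, coloc_flag = FALSE)
  st <- render_stack(g, sp, p1)
  img <- get_channel(st, "mve", z = 2L)
  tot <- sum(img)
  rc <- sum(row(img) * img) / tot
  cc <- sum(col(img) * img) / tot
  expect_lt(abs(rc - 96.3), 0.1)
  expect_lt(abs(cc - 80.7), 0.1)
})

test_that("simulate_field is deterministic and truth tables are consistent", {
  p <- tiny_params()
  f1 <- simulate_field(p, seed = 3L)
  f2 <- simulate_field(p, seed = 3L)
  expect_identical(f1$stack$data, f2$stack$data)
  expect_identical(f1$truth$spots, f2$truth$spots)

  # conservation: per-channel spot counts match truth records
  for (role in c("mve", "mirna_guide", "mirna_passenger")) {
    n_truth <- sum(f1$truth$spots$channel_role == role)
    n_tab <- switch(role, mve = sum(f1$truth$per_cell$n_mve),
                    mirna_guide = sum(f1$truth$per_cell$n_guide),
                    mirna_passenger = sum(f1$truth$per_cell$n_passenger))
    expect_equal(n_truth, n_tab)
  }
  # truth consistency: recomputed per-cell rates match stored values
  for (i in seq_len(nrow(f1$truth$per_cell))) {
    row <- f1$truth$per_cell[i, ]
    s <- f1$truth$spots[f1$truth$spots$cell_id == row$cell_id &
                          f1$truth$spots$channel_role == "mirna_guide", ]
    if (nrow(s) > 0)
      expect_equal(row$true_coloc_rate_guide, mean(s$coloc_flag))
  }
})

test_that("adding cells does not perturb earlier cells' puncta", {
  p2 <- tiny_params()
  p3 <- tiny_params()
  p3$n_cells <- 1L
  g2 <- generate_cell_geometry(p2)
  s2 <- place_puncta(g2, p2, seed = 5L)
  g1 <- list(cell_labels = g2$cell_labels, nucleus_labels = g2$nucleus_labels,
             cells = g2$cells[1, , drop = FALSE])
  s1 <- place_puncta(g1, p3, seed = 5L)
  a <- s2[s2$cell_id == 1, ]
  rownames(a) <- NULL
  expect_equal(a, s1)
})

test_that("per-cell true coloc rate tracks the fraction parameter", {
  # binomial control: mean over >= 50 cells within 3 SE of 0.5
  rates <- c(); n_spots <- 0
  for (j in 1:7) {
    p <- simulation_params(
      field_size_px = c(512, 512), pixel_size_nm = 160, n_cells = 8,
      coloc_fraction_guide = 0.5, seed = 100L + j,
      background_level = 0, spot_amplitude = 0, read_noise_sd = 0)
    g <- generate_cell_geometry(p)
    s <- place_puncta(g, p)
    guide <- s[s$channel_role == "mirna_guide", ]
    per <- tapply(guide$coloc_flag, guide$cell_id, mean)
    rates <- c(rates, per)
    n_spots <- n_spots + nrow(guide)
  }
  expect_gte(length(rates), 50)
  se <- sqrt(0.25 / n_spots)
  expect_lt(abs(mean(rates) - 0.5), max(3 * se, 0.05))
})
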