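# AND-gate, per-cell object co-localization, MVE classification, nuclear
# accumulation, Pearson correlation.

test_that("and_gate is an intersection: idempotent, commutative, bounded", {
  set.seed(5)
  a <- matrix(runif(16 * 16) < 0.4, 16, 16)
  b <- matrix(runif(16 * 16) < 0.4, 16, 16)
  expect_identical(and_gate(a, a), a)
  expect_identical(and_gate(a, b), and_gate(b, a))
  expect_lte(sum(and_gate(a, b)), min(sum(a), sum(b)))
  expect_false(any(and_gate(a, !a)))
  expect_error(and_gate(a, matrix(TRUE, 2, 2)), "dimensions")

  # hand-enumerated 4x4 case with a 3-pixel overlap
  m1 <- matrix(FALSE, 4, 4); m1[1, 1:3] <- TRUE; m1[2, 1] <- TRUE
  m2 <- matrix(FALSE, 4, 4); m2[1, 2:4] <- TRUE; m2[2, 1] <- TRUE
  expect_equal(sum(and_gate(m1, m2)), 3)
})

test_that("object co-localization counts match the brute-force oracle", {
  set.seed(77)
  for (rep in 1:5) {
    # random blob field in a single full-frame cell
    img <- matrix(0, 128, 128)
    n <- 25
    rs <- runif(n, 8, 120); cs <- runif(n, 8, 120)
    for (k in seq_len(n))
      img <- img + 50 * outer(exp(-((1:128) - rs[k])^2 / 8),
                              exp(-((1:128) - cs[k])^2 / 8))
    ss <- detect_puncta(img, 500, 160)
    other <- matrix(runif(128 * 128) < 0.1, 128, 128)
    # one interior cell covering the frame (border rows background)
    cl <- matrix(0L, 128, 128); cl[2:127, 2:127] <- 1L
    nl <- matrix(0L, 128, 128); nl[3:10, 3:10] <- 1L
    cm <- cell_map(nl, cl)
    ss <- assign_spots_to_cells(ss, cm)
    got <- object_coloc_counts(ss, other, cm)
    oracle <- oracle_object_coloc(ss$source_labels, other)
    s <- ss$spots
    in_cell <- which(!is.na(s$cell_id))
    expect_equal(got$n_coloc, sum(oracle[s$label[in_cell]]))
    expect_equal(got$n_obj, length(in_cell))
  }
})

test_that("object co-localization respects trivial mask relations", {
  p <- tiny_params(seed = 19L)
  f <- simulate_field(p)
  cm <- cell_map(f$truth$nucleus_labels, f$truth$cell_labels,
                 p$pixel_size_nm)
  img <- get_channel(max_intensity_projection(f$stack), "mve")
  ss <- assign_spots_to_cells(
    detect_puncta(img, p$mve_diameter_nm, p$pixel_size_nm), cm)
  dims <- dim(img)
  none <- object_coloc_counts(ss, matrix(FALSE, dims[1], dims[2]), cm)
  expect_true(all(none$n_coloc == 0))
  all_m <- object_coloc_counts(ss, matrix(TRUE, dims[1], dims[2]), cm)
  has <- all_m$n_obj > 0
  expect_true(all(all_m$coloc_rate[has] == 1))
  expect_true(all(is.na(all_m$coloc_rate[!has])))

  empty_cm <- cell_map(matrix(0L, dims[1], dims[2]),
                       matrix(0L, dims[1], dims[2]))
  expect_equal(nrow(object_coloc_counts(ss, matrix(TRUE, dims[1], dims[2]),
                                        empty_cm)), 0)
})

test_that("MVE classification is exclusive, exhaustive and seed-stable", {
  p <- tiny_params(seed = 23L)
  f <- simulate_field(p)
  cm <- cell_map(f$truth$nucleus_labels, f$truth$cell_labels,
                 p$pixel_size_nm)
  mip <- max_intensity_projection(f$stack)
  mve <- assign_spots_to_cells(
    detect_puncta(get_channel(mip, "mve"), p$mve_diameter_nm,
                  p$pixel_size_nm), cm)
  gm <- spot_mask(detect_puncta(get_channel(mip, "mirna_guide"),
                                p$mirna_spot_diameter_nm, p$pixel_size_nm))
  pm <- spot_mask(detect_puncta(get_channel(mip, "mirna_passenger"),
                                p$mirna_spot_diameter_nm, p$pixel_size_nm))
  cl <- classify_mves(mve, gm, pm, cm, sample_n = 5, seed = 4L)
  expect_true(all(cl$n_single + cl$n_guide_only + cl$n_passenger_only +
                    cl$n_both == cl$n_evaluated))
  expect_true(all(cl$n_evaluated <= pmin(5, cl$n_mve)))
  expect_true(all(cl$n_guide_pos == cl$n_guide_only + cl$n_both))
  cl2 <- classify_mves(mve, gm, pm, cm, sample_n = 5, seed = 4L)
  expect_identical(cl, cl2)

  dims <- dim(gm)
  none <- matrix(FALSE, dims[1], dims[2])
  cl0 <- classify_mves(mve, none, none, cm, sample_n = 5, seed = 4L)
  expect_true(all(cl0$n_single == cl0$n_evaluated))
  clg <- classify_mves(mve, matrix(TRUE, dims[1], dims[2]), none, cm,
                       sample_n = 5, seed = 4L)
  expect_true(all(clg$n_guide_only == clg$n_evaluated))
})

test_that("classification fractions follow the product law for independent strands", {
  # guide coloc 0.6, passenger 0.2, placed independently: expected MVE-level
  # category rates are products of the per-cell marginal hit fractions,
  # which the truth tables provide exactly (distinct MVEs hit per strand)
  counts <- c(single = 0, guide_only = 0, passenger_only = 0, both = 0)
  n_eval <- 0
  exp_g <- exp_p <- exp_b <- 0; w_tot <- 0
  for (j in 1:4) {
    p <- simulation_params(
      field_size_px = c(512, 512), pixel_size_nm = 160, n_cells = 8,
      coloc_fraction_guide = 0.6, coloc_fraction_passenger = 0.2,
      guide_spots_per_cell_mean = 10, passenger_spots_per_cell_mean = 10,
      mve_per_cell_mean = 10, shot_noise = FALSE, read_noise_sd = 0,
      background_level = 0, seed = 300L + j)
    f <- simulate_field(p)
    cm <- cell_map(f$truth$nucleus_labels, f$truth$cell_labels,
                   p$pixel_size_nm)
    mip <- max_intensity_projection(f$stack)
    mve <- assign_spots_to_cells(
      detect_puncta(get_channel(mip, "mve"), p$mve_diameter_nm,
                    p$pixel_size_nm), cm)
    gm <- spot_mask(detect_puncta(get_channel(mip, "mirna_guide"),
                                  p$mirna_spot_diameter_nm,
                                  p$pixel_size_nm))
    pm <- spot_mask(detect_puncta(get_channel(mip, "mirna_passenger"),
                                  p$mirna_spot_diameter_nm,
                                  p$pixel_size_nm))
    cl <- classify_mves(mve, gm, pm, cm, sample_n = 20, seed = 5L)
    counts <- counts + c(sum(cl$n_single), sum(cl$n_guide_only),
                         sum(cl$n_passenger_only), sum(cl$n_both))
    n_eval <- n_eval + sum(cl$n_evaluated)
    # per-cell marginal hit fractions from the truth (distinct MVEs hit)
    sp <- f$truth$spots
    for (id in f$truth$per_cell$cell_id) {
      m <- f$truth$per_cell$n_mve[f$truth$per_cell$cell_id == id]
      if (m == 0) next
      hit <- function(role) length(unique(
        sp$mve_id[sp$cell_id == id & sp$channel_role == role &
                    sp$coloc_flag])) / m
      pg_i <- hit("mirna_guide"); pp_i <- hit("mirna_passenger")
      w <- min(20, m)
      exp_g <- exp_g + w * pg_i
      exp_p <- exp_p + w * pp_i
      exp_b <- exp_b + w * pg_i * pp_i   # independence of the two strands
      w_tot <- w_tot + w
    }
  }
  pg <- exp_g / w_tot; pp <- exp_p / w_tot; pb <- exp_b / w_tot
  obs <- counts / n_eval
  expect_gt(w_tot, 300)
  expect_lt(abs(obs["both"] - pb), 0.07)
  expect_lt(abs(obs["guide_only"] - (pg - pb)), 0.07)
  expect_lt(abs(obs["passenger_only"] - (pp - pb)), 0.07)
  expect_lt(abs(obs["single"] - (1 - pg - pp + pb)), 0.07)
})

test_that("nuclear accumulation scoring follows the intensity ratio", {
  p <- tiny_params(shot_noise = FALSE, read_noise_sd = 0)
  f <- simulate_field(p)
  cm <- cell_map(f$truth$nucleus_labels, f$truth$cell_labels,
                 p$pixel_size_nm)
  uni <- matrix(7, 192, 192)
  res <- nuclear_accumulation(uni, cm, ratio_threshold = 1.5)
  expect_true(all(abs(res$per_cell$ratio - 1) < 1e-12))
  expect_equal(res$fraction_accumulated, 0)

  nuc_only <- (cm$nucleus_labels > 0) * 10 + 1
  res2 <- nuclear_accumulation(nuc_only, cm, ratio_threshold = 1.5)
  expect_equal(res2$fraction_accumulated, 1)
})

test_that("nuclear fraction in the simulator raises the accumulated fraction", {
  frac <- function(nf, seed) {
    p <- simulation_params(
      field_size_px = c(384, 384), pixel_size_nm = 160, n_cells = 4,
      nuclear_fraction_guide = nf, guide_spots_per_cell_mean = 25,
      seed = seed)
    f <- simulate_field(p)
    cm <- cell_map(f$truth$nucleus_labels, f$truth$cell_labels,
                   p$pixel_size_nm)
    mip <- max_intensity_projection(f$stack)
    nuclear_accumulation(get_channel(mip, "mirna_guide"), cm,
                         ratio_threshold = 1.2)$fraction_accumulated
  }
  for (seed in c(41L, 42L)) {
    expect_gt(frac(0.9, seed), frac(0, seed))
  }
})

test_that("Pearson coefficient has the affine and null properties", {
  set.seed(8)
  x <- matrix(runif(40 * 40), 40, 40)
  expect_equal(pearson_coefficient(x, x), 1)
  expect_equal(pearson_coefficient(x, 2 * x + 3), 1)
  expect_equal(pearson_coefficient(x, -0.5 * x + 1), -1)
  expect_error(pearson_coefficient(x, matrix(1, 40, 40)), "variance")
  m <- matrix(FALSE, 40, 40); m[1] <- TRUE
  expect_error(pearson_coefficient(x, x, m), "2 pixels")

  # null distribution: independent fields of 1e4 pixels, |r| small
  rs <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    pearson_coefficient(matrix(rnorm(1e4), 100, 100),
                        matrix(rnorm(1e4), 100, 100))
  }, numeric(1))
  expect_gte(mean(abs(rs) < 0.05), 0.95)
})
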