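# Synthetic fluorescence-microscopy generator: resealed-cell fields with
# known ground truth for every downstream stage.

CHANNEL_ROLES <- c("nucleus", "cytoplasm", "mve", "mirna_guide",
                   "mirna_passenger")

#' Simulation parameters for synthetic microscopy fields
#'
#' Constructs and validates the parameter set of the synthetic-field
#' generator. Defaults emulate the imaging geometry of the assay being
#' modeled: 9-slice z-stacks, ~500 nm CD63-positive MVE puncta and ~200 nm
#' miRNA spots, HeLa-sized cells. All lengths are physical (nm or um) and
#' are converted to pixels through `pixel_size_nm`.
#'
#' @param field_size_px integer (height, width) of the field in pixels.
#' @param n_z number of z slices (>= 1).
#' @param pixel_size_nm lateral sampling, nm per pixel.
#' @param n_cells number of cells to place (non-overlapping, fully inside
#'   the field).
#' @param cell_radius_um (min, max) cell semi-major axis, um.
#' @param nucleus_radius_um (min, max) nucleus semi-major axis, um; the max
#'   must be below the cell minimum so nuclei always fit inside their cell.
#' @param mve_per_cell_mean expected MVE count per cell (Poisson).
#' @param mve_diameter_nm MVE diameter, nm.
#' @param mirna_spot_diameter_nm miRNA spot diameter, nm.
#' @param guide_spots_per_cell_mean,passenger_spots_per_cell_mean expected
#'   miRNA spot counts per cell (Poisson).
#' @param coloc_fraction_guide,coloc_fraction_passenger fraction of miRNA
#'   spots placed inside an MVE footprint, in \[0, 1\].
#' @param nuclear_fraction_guide fraction of guide spots placed uniformly in
#'   the nucleus (never co-localized), in \[0, 1\].
#' @param psf_sigma_nm Gaussian optical blur (sigma), nm.
#' @param background_level per-channel background photon level, named after
#'   channel roles (unnamed scalar recycles).
#' @param spot_amplitude per-channel peak amplitude above background, named
#'   after channel roles (nucleus/cytoplasm entries set the fill amplitude
#'   of those region channels).
#' @param read_noise_sd additive Gaussian read noise SD, intensity units.
#' @param shot_noise apply per-pixel Poisson shot noise (disable for
#'   noise-free renders).
#' @param seed default seed used by [simulate_field()] when none is given.
#' @return object of class `simulation_params` (a validated list).
#' @export
simulation_params <- function(field_size_px = c(512L, 512L),
                              n_z = 9L,
                              pixel_size_nm = 80,
                              n_cells = 4L,
                              cell_radius_um = c(8, 10),
                              nucleus_radius_um = c(2.5, 4),
                              mve_per_cell_mean = 12,
                              mve_diameter_nm = 500,
                              mirna_spot_diameter_nm = 200,
                              guide_spots_per_cell_mean = 12,
                              passenger_spots_per_cell_mean = 8,
                              coloc_fraction_guide = 0.5,
                              coloc_fraction_passenger = 0.2,
                              nuclear_fraction_guide = 0,
                              psf_sigma_nm = 100,
                              background_level = c(nucleus = 20, cytoplasm = 20,
                                                   mve = 20, mirna_guide = 20,
                                                   mirna_passenger = 20),
                              spot_amplitude = c(nucleus = 150, cytoplasm = 80,
                                                 mve = 300, mirna_guide = 300,
                                                 mirna_passenger = 300),
                              read_noise_sd = 2,
                              shot_noise = TRUE,
                              seed = 1L) {
  expand_ch <- function(x, what) {
    if (is.null(names(x)) && length(x) == 1) {
      x <- rep(x, length(CHANNEL_ROLES)); names(x) <- CHANNEL_ROLES
    }
    if (!all(CHANNEL_ROLES %in% names(x)))
      stop(what, " must be named for every channel role")
    x <- x[CHANNEL_ROLES]
    if (any(x < 0)) stop(what, " must be non-negative")
    x
  }
  p <- list(
    field_size_px = as.integer(field_size_px),
    n_z = as.integer(n_z),
    pixel_size_nm = pixel_size_nm,
    n_cells = as.integer(n_cells),
    cell_radius_um = as.numeric(cell_radius_um),
    nucleus_radius_um = as.numeric(nucleus_radius_um),
    mve_per_cell_mean = mve_per_cell_mean,
    mve_diameter_nm = mve_diameter_nm,
    mirna_spot_diameter_nm = mirna_spot_diameter_nm,
    guide_spots_per_cell_mean = guide_spots_per_cell_mean,
    passenger_spots_per_cell_mean = passenger_spots_per_cell_mean,
    coloc_fraction_guide = coloc_fraction_guide,
    coloc_fraction_passenger = coloc_fraction_passenger,
    nuclear_fraction_guide = nuclear_fraction_guide,
    psf_sigma_nm = psf_sigma_nm,
    background_level = expand_ch(background_level, "background_level"),
    spot_amplitude = expand_ch(spot_amplitude, "spot_amplitude"),
    read_noise_sd = read_noise_sd,
    shot_noise = isTRUE(shot_noise),
    seed = as.integer(seed)
  )
  validate_simulation_params(p)
  class(p) <- "simulation_params"
  p
}

validate_simulation_params <- function(p) {
  stopifnot(
    length(p$field_size_px) == 2, all(p$field_size_px >= 1),
    p$n_z >= 1, p$pixel_size_nm > 0, p$n_cells >= 0,
    length(p$cell_radius_um) == 2, all(p$cell_radius_um > 0),
    p$cell_radius_um[1] <= p$cell_radius_um[2],
    length(p$nucleus_radius_um) == 2, all(p$nucleus_radius_um > 0),
    p$nucleus_radius_um[1] <= p$nucleus_radius_um[2],
    p$mve_per_cell_mean >= 0, p$mve_diameter_nm >= 0,
    p$mirna_spot_diameter_nm >= 0,
    p$guide_spots_per_cell_mean >= 0, p$passenger_spots_per_cell_mean >= 0,
    p$psf_sigma_nm >= 0, p$read_noise_sd >= 0
  )
  fr <- c(p$coloc_fraction_guide, p$coloc_fraction_passenger,
          p$nuclear_fraction_guide)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (p$nucleus_radius_um[2] >= p$cell_radius_um[1])
    stop("nucleus radius max must be below cell radius min")
  invisible(TRUE)
}

# nm -> px conversion for spot diameters; floors at 1 px so sub-resolution
# spots stay representable
diameter_px <- function(diameter_nm, pixel_size_nm) {
  max(1, diameter_nm / pixel_size_nm)
}

# FWHM-style diameter -> Gaussian sigma (d / (2 sqrt(2 ln 2)))
diameter_to_sigma <- function(d) d / (2 * sqrt(2 * log(2)))

#' Generate non-overlapping cell and nucleus geometry
#'
#' Places `n_cells` elliptical cells (random semi-axes and orientation) with
#' concentric elliptical nuclei. Cells are pairwise disjoint (guaranteed by
#' a center-distance test against the sum of semi-major axes) and wholly
#' inside the field. Placement is by rejection; if the requested count
#' cannot be placed, an error reports how many cells were achieved.
#'
#' @param params a [simulation_params()] object.
#' @param seed integer seed for the placement stream.
#' @param max_attempts placement attempts per cell before giving up.
#' @return list with `cell_labels` and `nucleus_labels` (HxW integer
#'   matrices) and `cells`, a data.frame of per-cell geometry
#'   (cell_id, centroid, semi-axes in px, orientation, border_touching).
#' @export
generate_cell_geometry <- function(params, seed = params$seed,
                                   max_attempts = 1000L) {
  validate_simulation_params(params)
  nr <- params$field_size_px[1]; nc <- params$field_size_px[2]
  cell_labels <- matrix(0L, nr, nc)
  nucleus_labels <- matrix(0L, nr, nc)
  cells <- data.frame(
    cell_id = integer(0), centroid_r = numeric(0), centroid_c = numeric(0),
    cell_a_px = numeric(0), cell_b_px = numeric(0), theta = numeric(0),
    nucleus_a_px = numeric(0), nucleus_b_px = numeric(0),
    border_touching = logical(0)
  )
  if (params$n_cells == 0)
    return(list(cell_labels = cell_labels, nucleus_labels = nucleus_labels,
                cells = cells))
  px_per_um <- 1000 / params$pixel_size_nm
  placed <- with_seed(mix_seed(seed, 1L), {
    out <- vector("list", params$n_cells)
    n_placed <- 0L
    for (i in seq_len(params$n_cells)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        a <- runif(1, params$cell_radius_um[1], params$cell_radius_um[2]) *
          px_per_um
        ecc <- runif(1, 0.7, 1)            # semi-minor / semi-major
        b <- a * ecc
        theta <- runif(1, 0, pi)
        if (2 * a + 4 > min(nr, nc))
          stop("cell diameter exceeds field size")
        cr <- runif(1, a + 2, nr - a - 1)
        cc <- runif(1, a + 2, nc - a - 1)
        clear <- TRUE
        if (n_placed > 0) {
          for (j in seq_len(n_placed)) {
            pj <- out[[j]]
            if ((cr - pj$cr)^2 + (cc - pj$cc)^2 <= (a + pj$a + 1)^2) {
              clear <- FALSE; break
            }
          }
        }
        if (clear) {
          na <- runif(1, params$nucleus_radius_um[1],
                      params$nucleus_radius_um[2]) * px_per_um
          nb <- na * runif(1, 0.75, 1)
          n_placed <- n_placed + 1L
          out[[n_placed]] <- list(cr = cr, cc = cc, a = a, b = b,
                                  theta = theta, na = na, nb = nb)
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop(sprintf(
          "cell placement failed: placed %d of %d cells without overlap",
          n_placed, params$n_cells))
    }
    out
  })
  for (i in seq_along(placed)) {
    g <- placed[[i]]
    cm <- ellipse_mask(nr, nc, g$cr, g$cc, g$a, g$b, g$theta)
    nm <- ellipse_mask(nr, nc, g$cr, g$cc, g$na, g$nb, g$theta)
    cell_labels[cm] <- i
    nucleus_labels[nm] <- i
    border <- any(cm[1, ]) || any(cm[nr, ]) || any(cm[, 1]) || any(cm[, nc])
    cells <- rbind(cells, data.frame(
      cell_id = i, centroid_r = g$cr, centroid_c = g$cc,
      cell_a_px = g$a, cell_b_px = g$b, theta = g$theta,
      nucleus_a_px = g$na, nucleus_b_px = g$nb,
      border_touching = border
    ))
  }
  list(cell_labels = cell_labels, nucleus_labels = nucleus_labels,
       cells = cells)
}

#' Place MVE and miRNA puncta with ground-truth co-localization flags
#'
#' MVE centers are uniform over each cell's cytoplasm (cell minus nucleus).
#' Each miRNA spot of a role is, independently: placed uniformly in the
#' nucleus with probability `nuclear_fraction` (guide only, never
#' co-localized); otherwise, with probability `coloc_fraction`, placed at a
#' uniformly chosen MVE center plus a uniform offset of less than a quarter
#' MVE diameter (co-localized, `coloc_flag` TRUE); or uniformly in the
#' cytoplasm (`coloc_flag` FALSE). Co-localized spots draw their MVE
#' without replacement (reshuffling once all MVEs are used), so each MVE is
#' equally likely marginally but spots spread across distinct MVEs —
#' otherwise spots sharing one MVE fuse into a single sub-resolution object
#' and deflate object-level co-localization counts. Each cell consumes its
#' own derived random sub-stream, so adding cells does not perturb earlier
#' cells.
#'
#' @param geometry result of [generate_cell_geometry()].
#' @param params a [simulation_params()] object.
#' @param seed integer seed for the placement stream.
#' @return data.frame of spots: channel_role, r_px, c_px, z, cell_id,
#'   mve_id (NA when not co-localized), coloc_flag.
#' @export
place_puncta <- function(geometry, params, seed = params$seed) {
  validate_simulation_params(params)
  cells <- geometry$cells
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    g <- cells[i, ]
    cyto_area <- sum(geometry$cell_labels == g$cell_id) -
      sum(geometry$nucleus_labels == g$cell_id)
    if (cyto_area <= 0) {
      warning(sprintf("cell %d has zero cytoplasm area; skipped", g$cell_id))
      next
    }
    rows[[length(rows) + 1L]] <- with_seed(mix_seed(seed, 2L, g$cell_id), {
      excl <- list(cr = g$centroid_r, cc = g$centroid_c,
                   a = g$nucleus_a_px, b = g$nucleus_b_px, theta = g$theta)
      n_mve <- rpois(1, params$mve_per_cell_mean)
      mve_xy <- sample_in_ellipse(n_mve, g$centroid_r, g$centroid_c,
                                  g$cell_a_px, g$cell_b_px, g$theta,
                                  excl = excl)
      mve_df <- if (n_mve > 0) data.frame(
        channel_role = "mve", r_px = mve_xy[, 1], c_px = mve_xy[, 2],
        z = sample.int(params$n_z, n_mve, replace = TRUE),
        cell_id = g$cell_id, mve_id = seq_len(n_mve), coloc_flag = FALSE
      ) else NULL
      place_role <- function(role, n_mean, coloc_fr, nuclear_fr) {
        n <- rpois(1, n_mean)
        if (n == 0) return(NULL)
        r <- numeric(n); c <- numeric(n)
        mve_id <- rep(NA_integer_, n); coloc <- logical(n)
        off_r <- params$mve_diameter_nm / 4 / params$pixel_size_nm
        mve_queue <- integer(0)   # without-replacement draw order
        for (k in seq_len(n)) {
          if (runif(1) < nuclear_fr) {
            p <- sample_in_ellipse(1, g$centroid_r, g$centroid_c,
                                   g$nucleus_a_px, g$nucleus_b_px, g$theta)
            r[k] <- p[1]; c[k] <- p[2]
          } else if (n_mve > 0 && runif(1) < coloc_fr) {
            if (length(mve_queue) == 0)
              mve_queue <- if (n_mve == 1) 1L else sample.int(n_mve)
            m <- mve_queue[1]
            mve_queue <- mve_queue[-1]
            ang <- runif(1, 0, 2 * pi)
            rad <- off_r * sqrt(runif(1))
            r[k] <- mve_xy[m, 1] + rad * sin(ang)
            c[k] <- mve_xy[m, 2] + rad * cos(ang)
            mve_id[k] <- m; coloc[k] <- TRUE
          } else {
            p <- sample_in_ellipse(1, g$centroid_r, g$centroid_c,
                                   g$cell_a_px, g$cell_b_px, g$theta,
                                   excl = excl)
            r[k] <- p[1]; c[k] <- p[2]
          }
        }
        data.frame(channel_role = role, r_px = r, c_px = c,
                   z = sample.int(params$n_z, n, replace = TRUE),
                   cell_id = g$cell_id, mve_id = mve_id, coloc_flag = coloc)
      }
      guide_df <- place_role("mirna_guide", params$guide_spots_per_cell_mean,
                             params$coloc_fraction_guide,
                             params$nuclear_fraction_guide)
      pass_df <- place_role("mirna_passenger",
                            params$passenger_spots_per_cell_mean,
                            params$coloc_fraction_passenger, 0)
      do.call(rbind, Filter(Negate(is.null), list(mve_df, guide_df, pass_df)))
    })
  }
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out))
    out <- data.frame(channel_role = character(0), r_px = numeric(0),
                      c_px = numeric(0), z = integer(0), cell_id = integer(0),
                      mve_id = integer(0), coloc_flag = logical(0))
  rownames(out) <- NULL
  out
}

# per-cell truth table recomputed from spot records
per_cell_truth <- function(geometry, spots) {
  ids <- geometry$cells$cell_id
  rate <- function(df) if (nrow(df) > 0) mean(df$coloc_flag) else NA_real_
  do.call(rbind, lapply(ids, function(id) {
    s <- spots[spots$cell_id == id, , drop = FALSE]
    data.frame(
      cell_id = id,
      n_mve = sum(s$channel_role == "mve"),
      n_guide = sum(s$channel_role == "mirna_guide"),
      n_passenger = sum(s$channel_role == "mirna_passenger"),
      true_coloc_rate_guide =
        rate(s[s$channel_role == "mirna_guide", , drop = FALSE]),
      true_coloc_rate_passenger =
        rate(s[s$channel_role == "mirna_passenger", , drop = FALSE])
    )
  }))
}

#' Render a multi-channel z-stack from geometry and spots
#'
#' Region channels (nucleus, cytoplasm) are filled at their amplitude in
#' every slice; each punctum is an isotropic Gaussian of sigma =
#' diameter / (2 sqrt(2 ln 2)) combined in quadrature with the PSF sigma,
#' rendered at its peak amplitude in its own z slice. Per-pixel Poisson
#' shot noise (if `shot_noise`) is followed by additive Gaussian read
#' noise; intensities are clipped at 0.
#'
#' @param geometry result of [generate_cell_geometry()].
#' @param spots data.frame from [place_puncta()].
#' @param params a [simulation_params()] object.
#' @param seed integer seed for the noise stream.
#' @return an `image_stack`: list with `data` (channels x z x H x W array),
#'   `channel_roles`, `pixel_size_nm`.
#' @export
render_stack <- function(geometry, spots, params, seed = params$seed) {
  validate_simulation_params(params)
  nr <- params$field_size_px[1]; nc <- params$field_size_px[2]
  nz <- params$n_z
  n_ch <- length(CHANNEL_ROLES)
  data <- array(0, dim = c(n_ch, nz, nr, nc))
  amp <- params$spot_amplitude
  bg <- params$background_level
  sig_psf <- params$psf_sigma_nm / params$pixel_size_nm
  spot_sigma <- function(d_nm) {
    d_px <- diameter_px(d_nm, params$pixel_size_nm)
    sqrt(diameter_to_sigma(d_px)^2 + sig_psf^2)
  }
  sig <- c(mve = spot_sigma(params$mve_diameter_nm),
           mirna_guide = spot_sigma(params$mirna_spot_diameter_nm),
           mirna_passenger = spot_sigma(params$mirna_spot_diameter_nm))

  region <- list(nucleus = geometry$nucleus_labels > 0,
                 cytoplasm = geometry$cell_labels > 0)
  for (role in names(region)) {
    ci <- match(role, CHANNEL_ROLES)
    plane <- bg[[role]] + amp[[role]] * region[[role]]
    for (z in seq_len(nz)) data[ci, z, , ] <- plane
  }
  for (role in names(sig)) {
    ci <- match(role, CHANNEL_ROLES)
    for (z in seq_len(nz)) data[ci, z, , ] <- bg[[role]]
    s <- spots[spots$channel_role == role, , drop = FALSE]
    if (nrow(s) == 0) next
    sg <- sig[[role]]
    half <- ceiling(4 * sg)
    for (k in seq_len(nrow(s))) {
      r0 <- max(1L, floor(s$r_px[k] - half))
      r1 <- min(nr, ceiling(s$r_px[k] + half))
      c0 <- max(1L, floor(s$c_px[k] - half))
      c1 <- min(nc, ceiling(s$c_px[k] + half))
      if (r0 > r1 || c0 > c1) next
      rs <- r0:r1; cs <- c0:c1
      gr <- exp(-(rs - s$r_px[k])^2 / (2 * sg^2))
      gc <- exp(-(cs - s$c_px[k])^2 / (2 * sg^2))
      patch <- amp[[role]] * outer(gr, gc)
      z <- s$z[k]
      data[ci, z, rs, cs] <- data[ci, z, rs, cs] + patch
    }
  }
  # noise, seeded per channel so channel sets are order-stable
  for (ci in seq_len(n_ch)) {
    clean <- data[ci, , , ]
    if (max(clean) == 0 && params$read_noise_sd == 0) next
    data[ci, , , ] <- with_seed(mix_seed(seed, 3L, ci), {
      x <- if (params$shot_noise) {
        v <- rpois(length(clean), clean)
        storage.mode(v) <- "double"
        array(v, dim = dim(clean))
      } else clean
      if (params$read_noise_sd > 0)
        x <- x + array(rnorm(length(x), 0, params$read_noise_sd), dim(x))
      pmax(x, 0)
    })
  }
  image_stack(data, CHANNEL_ROLES, params$pixel_size_nm)
}

#' Construct an image stack container
#'
#' @param data numeric array, channels x z x H x W, non-negative.
#' @param channel_roles character vector naming the role of each channel.
#' @param pixel_size_nm lateral pixel size in nm.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(data, channel_roles, pixel_size_nm) {
  stopifnot(length(dim(data)) == 4, dim(data)[1] == length(channel_roles),
            pixel_size_nm > 0)
  if (any(data < 0)) stop("image_stack intensities must be non-negative")
  if (anyDuplicated(channel_roles)) stop("channel roles must be unique")
  structure(list(data = data, channel_roles = channel_roles,
                 pixel_size_nm = pixel_size_nm),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d channels x %d z x %d x %d px (%g nm/px)\n",
              d[1], d[2], d[3], d[4], x$pixel_size_nm))
  cat(" roles:", paste(x$channel_roles, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate one field: geometry, spots, rendered stack and ground truth
#'
#' Deterministic composition of [generate_cell_geometry()],
#' [place_puncta()] and [render_stack()] under sub-seeds derived from one
#' seed. Writes nothing.
#'
#' @param params a [simulation_params()] object.
#' @param seed integer master seed (defaults to `params$seed`).
#' @return list with `stack` (an `image_stack`) and `truth` (list of
#'   `spots`, `cells`, `per_cell`, plus the raw geometry label images).
#' @export
simulate_field <- function(params, seed = params$seed) {
  geometry <- generate_cell_geometry(params, seed = seed)
  spots <- place_puncta(geometry, params, seed = seed)
  stack <- render_stack(geometry, spots, params, seed = seed)
  truth <- list(spots = spots,
                cells = geometry$cells,
                per_cell = per_cell_truth(geometry, spots),
                cell_labels = geometry$cell_labels,
                nucleus_labels = geometry$nucleus_labels)
  list(stack = stack, truth = truth)
}
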