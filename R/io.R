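# File I/O: TIFF stacks with JSON sidecar metadata, ground-truth and
# result CSV tables, and YAML/JSON pipeline configuration.

#' Write an image stack as a multi-page 32-bit float TIFF
#'
#' Pages are ordered channel-major (all z of channel 1, then channel 2,
#' ...). Samples are stored as 32-bit values in \[0, 1\]; intensities are
#' divided by a scale factor (the smallest power of two at or above the
#' data maximum) that is recorded, together with channel roles, layout and
#' pixel size, in a JSON sidecar `<path>.json`. The round trip preserves
#' intensities to 32-bit sample quantization (relative error below 1e-9 of
#' the full scale), and writing the same stack twice produces identical
#' bytes.
#'
#' @param stack an `image_stack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  mx <- max(stack$data)
  scale <- if (mx > 0) 2^ceiling(log2(mx)) else 1
  pages <- vector("list", d[1] * d[2])
  i <- 0L
  for (ci in seq_len(d[1])) for (z in seq_len(d[2])) {
    i <- i + 1L
    pages[[i]] <- matrix(stack$data[ci, z, , ], d[3], d[4]) / scale
  }
  n_written <- tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  if (n_written != length(pages)) stop("failed to write TIFF: ", path)
  meta <- list(format = "punctacoloc-stack", version = 1L,
               channel_roles = stack$channel_roles,
               n_channels = d[1], n_z = d[2],
               height = d[3], width = d[4],
               pixel_size_nm = stack$pixel_size_nm,
               intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path TIFF path (the `<path>.json` sidecar must be present).
#' @param required_roles channel roles that must be resolvable; a missing
#'   role raises a "role unresolved" error.
#' @return an `image_stack`.
#' @export
read_stack <- function(path, required_roles = NULL) {
  side <- paste0(path, ".json")
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(side)) stop("missing channel-map sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  roles <- meta$channel_roles
  for (r in required_roles)
    if (!r %in% roles) stop(sprintf("role unresolved: %s", r))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != meta$n_channels * meta$n_z)
    stop("page count does not match sidecar layout")
  data <- array(0, dim = c(meta$n_channels, meta$n_z, meta$height,
                           meta$width))
  i <- 0L
  for (ci in seq_len(meta$n_channels)) for (z in seq_len(meta$n_z)) {
    i <- i + 1L
    data[ci, z, , ] <- pages[[i]] * meta$intensity_scale
  }
  image_stack(data, roles, meta$pixel_size_nm)
}

#' Write ground-truth tables as CSV
#'
#' @param truth the `truth` element of [simulate_field()].
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "spots.csv")
  p2 <- file.path(dir, "cells.csv")
  write.csv(truth$spots, p1, row.names = FALSE)
  write.csv(truth$cells, p2, row.names = FALSE)
  invisible(c(spots = p1, cells = p2))
}

#' Write per-cell and summary result tables plus a run manifest
#'
#' Column order is stable; missing values are written as `NA`. The
#' manifest (JSON) records the effective configuration, seed and package
#' version, so identical inputs reproduce byte-identical outputs.
#'
#' @param results a result bundle from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
write_tables <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (nm in c("per_cell", "classification", "summary")) {
    if (!is.null(results[[nm]])) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      write.csv(results[[nm]], p, row.names = FALSE)
      paths[nm] <- p
    }
  }
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(results$manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths["manifest"] <- mp
  invisible(paths)
}

#' Assemble and validate a pipeline configuration
#'
#' All tunable parameters of the analysis stages with their defaults. The
#' configuration round-trips losslessly through YAML via [write_config()] /
#' [read_config()].
#'
#' @param simulate `simulation_params` to generate the input field, or NULL
#'   to read `input_stack` from disk.
#' @param input_stack path to a TIFF stack (ignored when `simulate` given).
#' @param smoothing_sigma_px Gaussian smoothing for segmentation.
#' @param threshold_method global threshold method: otsu, percentile, fixed.
#' @param nucleus_min_area_px minimum nucleus area.
#' @param mve_diameter_nm,mirna_spot_diameter_nm expected object diameters
#'   for LoG detection.
#' @param spot_min_area_px,spot_max_area_px puncta area filter.
#' @param min_overlap_px AND-gate object overlap threshold.
#' @param sample_n MVEs sampled per cell for classification.
#' @param nuclear_ratio_threshold nuclear-accumulation ratio cutoff.
#' @param seed master seed for all stage sub-streams.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, input_stack = NULL,
                            smoothing_sigma_px = 2,
                            threshold_method = "otsu",
                            nucleus_min_area_px = 50,
                            mve_diameter_nm = 500,
                            mirna_spot_diameter_nm = 200,
                            spot_min_area_px = 1, spot_max_area_px = Inf,
                            min_overlap_px = 1, sample_n = 20,
                            nuclear_ratio_threshold = 1.5, seed = 1L) {
  stopifnot(threshold_method %in% c("otsu", "percentile", "fixed"),
            smoothing_sigma_px >= 0, nucleus_min_area_px >= 0,
            mve_diameter_nm > 0, mirna_spot_diameter_nm > 0,
            spot_min_area_px >= 0, min_overlap_px >= 1, sample_n >= 1,
            nuclear_ratio_threshold > 0)
  if (is.null(simulate) && is.null(input_stack))
    stop("config needs either a simulate block or an input_stack path")
  cfg <- list(simulate = simulate, input_stack = input_stack,
              smoothing_sigma_px = smoothing_sigma_px,
              threshold_method = threshold_method,
              nucleus_min_area_px = nucleus_min_area_px,
              mve_diameter_nm = mve_diameter_nm,
              mirna_spot_diameter_nm = mirna_spot_diameter_nm,
              spot_min_area_px = spot_min_area_px,
              spot_max_area_px = spot_max_area_px,
              min_overlap_px = min_overlap_px, sample_n = sample_n,
              nuclear_ratio_threshold = nuclear_ratio_threshold,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write a pipeline configuration to YAML
#'
#' @param config a `pipeline_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  if (!is.null(x$simulate)) {
    x$simulate <- unclass(x$simulate)
    # yaml drops names of atomic vectors; store per-channel maps as lists
    x$simulate$background_level <- as.list(x$simulate$background_level)
    x$simulate$spot_amplitude <- as.list(x$simulate$spot_amplitude)
  }
  x$spot_max_area_px <- if (is.finite(x$spot_max_area_px))
    x$spot_max_area_px else ".inf"
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file written by [write_config()].
#' @return a validated `pipeline_config`.
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (identical(x$spot_max_area_px, ".inf")) x$spot_max_area_px <- Inf
  sim <- NULL
  if (!is.null(x$simulate)) {
    s <- x$simulate
    sim <- simulation_params(
      field_size_px = s$field_size_px, n_z = s$n_z,
      pixel_size_nm = s$pixel_size_nm, n_cells = s$n_cells,
      cell_radius_um = s$cell_radius_um,
      nucleus_radius_um = s$nucleus_radius_um,
      mve_per_cell_mean = s$mve_per_cell_mean,
      mve_diameter_nm = s$mve_diameter_nm,
      mirna_spot_diameter_nm = s$mirna_spot_diameter_nm,
      guide_spots_per_cell_mean = s$guide_spots_per_cell_mean,
      passenger_spots_per_cell_mean = s$passenger_spots_per_cell_mean,
      coloc_fraction_guide = s$coloc_fraction_guide,
      coloc_fraction_passenger = s$coloc_fraction_passenger,
      nuclear_fraction_guide = s$nuclear_fraction_guide,
      psf_sigma_nm = s$psf_sigma_nm,
      background_level = unlist(s$background_level),
      spot_amplitude = unlist(s$spot_amplitude),
      read_noise_sd = s$read_noise_sd, shot_noise = s$shot_noise,
      seed = s$seed)
  }
  pipeline_config(
    simulate = sim, input_stack = x$input_stack,
    smoothing_sigma_px = x$smoothing_sigma_px,
    threshold_method = x$threshold_method,
    nucleus_min_area_px = x$nucleus_min_area_px,
    mve_diameter_nm = x$mve_diameter_nm,
    mirna_spot_diameter_nm = x$mirna_spot_diameter_nm,
    spot_min_area_px = x$spot_min_area_px,
    spot_max_area_px = x$spot_max_area_px,
    min_overlap_px = x$min_overlap_px, sample_n = x$sample_n,
    nuclear_ratio_threshold = x$nuclear_ratio_threshold, seed = x$seed)
}
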