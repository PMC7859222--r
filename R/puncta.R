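# Puncta detection: Laplacian-of-Gaussian filtering, thresholding on the
# response, 8-connected labeling, and per-cell assignment.

#' Laplacian-of-Gaussian blob response
#'
#' Convolves the image with a scale-normalized LoG kernel and negates it,
#' so bright blobs of radius ~ sqrt(2) sigma give positive peaks. The
#' discrete kernel is mean-subtracted so a constant image maps to an
#' exactly zero response. Boundary handling replicates edge pixels.
#'
#' @param image 2D numeric matrix.
#' @param sigma_px Gaussian scale in pixels (> 0).
#' @return response matrix, same dimensions as the input.
#' @export
log_filter <- function(image, sigma_px) {
  stopifnot(is.matrix(image))
  if (!is.numeric(sigma_px) || sigma_px <= 0)
    stop("sigma_px must be positive")
  half <- max(1L, ceiling(4 * sigma_px))
  ax <- -half:half
  g <- exp(-ax^2 / (2 * sigma_px^2))
  G <- outer(g, g)
  r2 <- outer(ax^2, ax^2, `+`)
  K <- (r2 - 2 * sigma_px^2) / sigma_px^4 * G   # Laplacian of Gaussian
  K <- K / sum(G)
  K <- K - mean(K)                              # exact zero on constants
  resp <- EBImage::filter2(EBImage::as.Image(image), K,
                           boundary = "replicate")
  -sigma_px^2 * as.matrix(resp)                 # scale-normalized, negated
}

#' Detect puncta by LoG filtering and thresholding of the response
#'
#' The LoG scale is derived from the physical spot diameter as
#' sigma_px = d_px / (2 sqrt(2)) with d_px = max(1, d_nm / pixel_size_nm),
#' placing the LoG zero-crossing at the spot radius. The threshold
#' (Otsu by default) is computed on the positive response values only;
#' retained pixels are labeled with 8-connectivity and filtered by area.
#' Intensity statistics are measured on the original image.
#'
#' @param image 2D numeric matrix.
#' @param expected_diameter_nm physical spot diameter, nm.
#' @param pixel_size_nm lateral pixel size, nm.
#' @param threshold_method one of "otsu", "percentile", "fixed".
#' @param min_area_px,max_area_px component area filter (inclusive).
#' @param fixed_threshold,percentile parameters of the non-Otsu methods.
#' @param channel_role recorded in the result.
#' @return a `spot_set`: list with `channel_role`, `spots` (data.frame:
#'   label, r_px, c_px, area_px, mean_intensity, total_intensity,
#'   equivalent_diameter_px, cell_id), `source_mask` and `source_labels`.
#' @export
detect_puncta <- function(image, expected_diameter_nm, pixel_size_nm,
                          threshold_method = "otsu", min_area_px = 1,
                          max_area_px = Inf, fixed_threshold = NULL,
                          percentile = 0.99, channel_role = NA_character_) {
  stopifnot(is.matrix(image), expected_diameter_nm > 0, pixel_size_nm > 0)
  d_px <- diameter_px(expected_diameter_nm, pixel_size_nm)
  sigma <- d_px / (2 * sqrt(2))
  resp <- log_filter(image, sigma)
  pos <- resp[resp > 0]
  if (length(pos) == 0 || diff(range(pos)) <= 0)
    return(empty_spot_set(dim(image), channel_role))
  thr <- threshold_value(pos, threshold_method, fixed = fixed_threshold,
                         percentile = percentile)
  mask <- resp >= thr & resp > 0
  lab <- label_components(mask, connectivity = 8)
  if (max(lab) == 0) return(empty_spot_set(dim(image), channel_role))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area_px & areas <= max_area_px)
  if (length(keep) == 0) return(empty_spot_set(dim(image), channel_role))
  remap <- integer(length(areas)); remap[keep] <- seq_along(keep)
  newlab <- matrix(0L, nrow(lab), ncol(lab))
  p <- lab > 0
  newlab[p] <- remap[lab[p]]
  idx <- which(newlab > 0, arr.ind = TRUE)
  l <- newlab[newlab > 0]
  inten <- image[newlab > 0]
  area <- tabulate(l)
  lf <- factor(l, levels = seq_along(area))  # keep numeric label order
  spots <- data.frame(
    label = seq_along(area),
    r_px = as.numeric(tapply(idx[, 1], lf, mean)),
    c_px = as.numeric(tapply(idx[, 2], lf, mean)),
    area_px = area,
    mean_intensity = as.numeric(tapply(inten, lf, mean)),
    total_intensity = as.numeric(tapply(inten, lf, sum)),
    cell_id = NA_integer_
  )
  spots$equivalent_diameter_px <- 2 * sqrt(spots$area_px / pi)
  structure(list(channel_role = channel_role, spots = spots,
                 source_mask = newlab > 0, source_labels = newlab),
            class = "spot_set")
}

empty_spot_set <- function(dims, channel_role) {
  structure(list(
    channel_role = channel_role,
    spots = data.frame(label = integer(0), r_px = numeric(0),
                       c_px = numeric(0), area_px = integer(0),
                       mean_intensity = numeric(0),
                       total_intensity = numeric(0),
                       cell_id = integer(0),
                       equivalent_diameter_px = numeric(0)),
    source_mask = matrix(FALSE, dims[1], dims[2]),
    source_labels = matrix(0L, dims[1], dims[2])
  ), class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("spot_set (%s): %d spots on %d x %d px\n",
              x$channel_role, nrow(x$spots),
              nrow(x$source_mask), ncol(x$source_mask)))
  invisible(x)
}

#' Binary mask of all retained spot pixels
#'
#' @param spot_set a `spot_set`.
#' @return logical matrix (the union of spot components).
#' @export
spot_mask <- function(spot_set) {
  stopifnot(inherits(spot_set, "spot_set"))
  spot_set$source_mask
}

#' Assign detected spots to cells by centroid
#'
#' Each spot's `cell_id` is the cell label at its (rounded) centroid pixel.
#' Spots on background or inside border-touching cells get `cell_id` NA and
#' are excluded from per-cell summaries.
#'
#' @param spot_set a `spot_set`.
#' @param cm a `cell_map` of the same dimensions.
#' @return the `spot_set` with `spots$cell_id` filled in.
#' @export
assign_spots_to_cells <- function(spot_set, cm) {
  stopifnot(inherits(spot_set, "spot_set"), inherits(cm, "cell_map"))
  if (!all(dim(spot_set$source_mask) == dim(cm$cell_labels)))
    stop("spot set and cell map dimensions differ")
  s <- spot_set$spots
  if (nrow(s) == 0) return(spot_set)
  r <- pmin(pmax(round(s$r_px), 1), nrow(cm$cell_labels))
  c <- pmin(pmax(round(s$c_px), 1), ncol(cm$cell_labels))
  id <- cm$cell_labels[cbind(r, c)]
  id[id == 0 | id %in% cm$border_touching] <- NA_integer_
  spot_set$spots$cell_id <- as.integer(id)
  spot_set
}
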