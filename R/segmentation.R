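# Single-cell segmentation: maximum-intensity projection, nucleus
# detection, and nucleus-seeded cell partitioning of the cytoplasm channel.

#' Maximum-intensity projection of an image stack
#'
#' Per channel and per pixel, the maximum over z. Channel roles and pixel
#' size are preserved.
#'
#' @param stack an `image_stack`.
#' @return an `image_mip`: list with `data` (channels x H x W), `channel_roles`,
#'   `pixel_size_nm`.
#' @export
max_intensity_projection <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  if (any(d == 0)) stop("empty stack: cannot project")
  out <- array(0, dim = d[c(1, 3, 4)])
  for (ci in seq_len(d[1])) {
    acc <- matrix(stack$data[ci, 1, , ], d[3], d[4])
    if (d[2] > 1) for (z in 2:d[2])
      acc <- pmax(acc, matrix(stack$data[ci, z, , ], d[3], d[4]))
    out[ci, , ] <- acc
  }
  structure(list(data = out, channel_roles = stack$channel_roles,
                 pixel_size_nm = stack$pixel_size_nm),
            class = "image_mip")
}

#' Extract one channel of a projected field as a matrix
#'
#' @param mip an `image_mip` (or `image_stack`, in which case `z` selects a
#'   slice).
#' @param role channel role name.
#' @param z slice index when extracting from a stack.
#' @return numeric H x W matrix.
#' @export
get_channel <- function(mip, role, z = NULL) {
  ci <- match(role, mip$channel_roles)
  if (is.na(ci)) stop(sprintf("role unresolved: %s", role))
  if (inherits(mip, "image_stack")) {
    if (is.null(z)) stop("z slice required when reading from a stack")
    d <- dim(mip$data)
    return(matrix(mip$data[ci, z, , ], d[3], d[4]))
  }
  d <- dim(mip$data)
  matrix(mip$data[ci, , ], d[2], d[3])
}

# Gaussian smoothing via EBImage; returns a plain matrix
smooth_image <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  as.matrix(EBImage::gblur(EBImage::as.Image(img), sigma = sigma_px))
}

#' Segment nuclei from the nucleus-stain channel
#'
#' Gaussian smoothing, global threshold (Otsu by default), hole filling,
#' then a distance-transform watershed to split touching nuclei; components
#' below `min_area_px` are discarded. Labels are consecutive positive
#' integers. A constant image yields zero nuclei with a warning.
#'
#' @param nucleus_image 2D non-negative matrix.
#' @param smoothing_sigma_px Gaussian sigma in px.
#' @param threshold_method one of "otsu", "percentile", "fixed".
#' @param min_area_px minimum component area kept.
#' @param fixed_threshold,percentile parameters of the non-Otsu methods.
#' @param max_foreground_fraction reject the thresholded mask (returning
#'   zero nuclei, with a warning) when it covers more than this fraction of
#'   the field; a global threshold on a field without nuclei splits the
#'   noise distribution near its middle, so a ~50% foreground is the
#'   signature of an empty field, while genuine nuclei cover far less.
#' @return integer label matrix.
#' @export
segment_nuclei <- function(nucleus_image, smoothing_sigma_px = 2,
                           threshold_method = "otsu", min_area_px = 50,
                           fixed_threshold = NULL, percentile = 0.99,
                           max_foreground_fraction = 0.4) {
  stopifnot(is.matrix(nucleus_image), all(nucleus_image >= 0))
  sm <- smooth_image(nucleus_image, smoothing_sigma_px)
  if (diff(range(sm)) <= 0) {
    warning("constant nucleus image: no threshold, returning zero nuclei")
    return(matrix(0L, nrow(sm), ncol(sm)))
  }
  thr <- threshold_value(as.numeric(sm), threshold_method,
                         fixed = fixed_threshold, percentile = percentile)
  mask <- sm >= thr
  if (mean(mask) > max_foreground_fraction) {
    warning("no distinct nuclear foreground: threshold covers ",
            round(100 * mean(mask)), "% of the field, returning zero nuclei")
    return(matrix(0L, nrow(sm), ncol(sm)))
  }
  if (!any(mask)) return(matrix(0L, nrow(sm), ncol(sm)))
  mask <- as.matrix(EBImage::fillHull(EBImage::as.Image(mask * 1))) > 0
  dm <- EBImage::distmap(EBImage::as.Image(mask * 1))
  lab <- as.matrix(EBImage::watershed(dm, tolerance = 1, ext = 1))
  # drop small components, relabel consecutively
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area_px)
  remap <- integer(length(areas))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0
  out[pos] <- remap[lab[pos]]
  out
}

#' Partition the cytoplasm channel into single cells seeded on nuclei
#'
#' A foreground mask is thresholded from the smoothed cytoplasm channel and
#' unioned with the nucleus masks; a seeded watershed (Voronoi-style
#' propagation on image intensity, seeds = nuclei) partitions the
#' foreground into one cell per nucleus. Nuclei without any surrounding
#' cytoplasm foreground are dropped. Cells touching the image border are
#' flagged `border_touching` and excluded from per-cell statistics
#' downstream.
#'
#' @param cytoplasm_image 2D non-negative matrix.
#' @param nucleus_labels label matrix from [segment_nuclei()].
#' @param smoothing_sigma_px Gaussian sigma in px.
#' @param threshold_method one of "otsu", "percentile", "fixed".
#' @param fixed_threshold,percentile parameters of the non-Otsu methods.
#' @param pixel_size_nm recorded in the result for nm conversions.
#' @return a `cell_map`: list with `nucleus_labels`, `cell_labels`,
#'   `nucleus_to_cell`, `border_touching` (integer ids), `pixel_size_nm`.
#' @export
segment_cells <- function(cytoplasm_image, nucleus_labels,
                          smoothing_sigma_px = 2, threshold_method = "otsu",
                          fixed_threshold = NULL, percentile = 0.99,
                          pixel_size_nm = NA_real_) {
  stopifnot(is.matrix(cytoplasm_image),
            all(dim(cytoplasm_image) == dim(nucleus_labels)))
  nr <- nrow(cytoplasm_image); nc <- ncol(cytoplasm_image)
  empty <- function() cell_map(matrix(0L, nr, nc), matrix(0L, nr, nc),
                               pixel_size_nm)
  if (max(nucleus_labels) == 0) return(empty())
  sm <- smooth_image(cytoplasm_image, smoothing_sigma_px)
  fg <- if (diff(range(sm)) <= 0) matrix(FALSE, nr, nc) else {
    thr <- threshold_value(as.numeric(sm), threshold_method,
                           fixed = fixed_threshold, percentile = percentile)
    sm >= thr
  }
  fg <- fg | nucleus_labels > 0
  cells <- as.matrix(EBImage::propagate(
    EBImage::as.Image(sm), EBImage::as.Image(nucleus_labels),
    mask = EBImage::as.Image(fg * 1)))
  storage.mode(cells) <- "integer"
  # drop nuclei with no surrounding cytoplasm (cell == nucleus extent)
  ids <- sort(unique(cells[cells > 0]))
  cell_area <- tabulate(cells[cells > 0], nbins = max(ids))
  nuc_area <- tabulate(nucleus_labels[nucleus_labels > 0], nbins = max(ids))
  dropped <- ids[cell_area[ids] <= nuc_area[ids]]
  if (length(dropped) > 0) {
    cells[cells %in% dropped] <- 0L
    nucleus_labels[nucleus_labels %in% dropped] <- 0L
  }
  cell_map(nucleus_labels, cells, pixel_size_nm)
}

#' Construct (and validate) a cell map
#'
#' @param nucleus_labels,cell_labels H x W integer label matrices; each
#'   nucleus must lie inside the same-labeled cell.
#' @param pixel_size_nm lateral pixel size, NA when unknown.
#' @return object of class `cell_map` with `border_touching` computed from
#'   `cell_labels`.
#' @export
cell_map <- function(nucleus_labels, cell_labels, pixel_size_nm = NA_real_) {
  stopifnot(all(dim(nucleus_labels) == dim(cell_labels)))
  storage.mode(nucleus_labels) <- "integer"
  storage.mode(cell_labels) <- "integer"
  nuc_ids <- sort(unique(nucleus_labels[nucleus_labels > 0]))
  mism <- nucleus_labels > 0 & cell_labels != nucleus_labels
  if (any(mism))
    stop("each nucleus pixel must lie inside its own cell's pixels")
  nr <- nrow(cell_labels); nc <- ncol(cell_labels)
  border <- unique(c(cell_labels[1, ], cell_labels[nr, ],
                     cell_labels[, 1], cell_labels[, nc]))
  border <- sort(border[border > 0])
  structure(list(
    nucleus_labels = nucleus_labels,
    cell_labels = cell_labels,
    nucleus_to_cell = stats::setNames(nuc_ids, nuc_ids),
    border_touching = border,
    pixel_size_nm = pixel_size_nm
  ), class = "cell_map")
}

#' Cell ids retained for per-cell statistics (border-touching excluded)
#'
#' @param cm a `cell_map`.
#' @return sorted integer vector of cell ids.
#' @export
retained_cells <- function(cm) {
  ids <- sort(unique(cm$cell_labels[cm$cell_labels > 0]))
  setdiff(ids, cm$border_touching)
}

#' Cytoplasmic region (cell minus nucleus) of one cell
#'
#' @param cm a `cell_map`.
#' @param cell_id a cell label present in the map.
#' @return logical H x W mask.
#' @export
cytoplasm_region <- function(cm, cell_id) {
  stopifnot(inherits(cm, "cell_map"))
  if (!any(cm$cell_labels == cell_id))
    stop(sprintf("unknown cell_id: %s", cell_id))
  cm$cell_labels == cell_id & cm$nucleus_labels != cell_id
}
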