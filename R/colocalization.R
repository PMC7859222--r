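# Object-based co-localization: AND-gated mask intersection, per-cell
# counting, random-sampled MVE classification, nuclear-accumulation
# scoring, and pixelwise Pearson correlation.

#' AND-gate of two binary masks
#'
#' Pixelwise logical intersection; commutative, idempotent, and contained
#' in each input.
#'
#' @param mask_a,mask_b logical (or 0/1) matrices of identical dimensions.
#' @return logical matrix.
#' @export
and_gate <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b)))
    stop("mask dimensions differ")
  (mask_a != 0) & (mask_b != 0)
}

#' Per-cell object co-localization counts
#'
#' An object of `query_spots` counts as co-localized iff its pixels share
#' at least `min_overlap_px` pixels with the AND-gate of the query mask and
#' `other_mask`. Counts are aggregated over retained (non-border) cells;
#' `coloc_rate` is `n_coloc / n_obj`, reported as NA when a cell holds no
#' objects.
#'
#' @param query_spots a `spot_set` with cell assignments (see
#'   [assign_spots_to_cells()]).
#' @param other_mask binary mask of the partner channel's objects.
#' @param cm a `cell_map`.
#' @param min_overlap_px minimum shared pixel count (default 1).
#' @return data.frame with cell_id, n_obj, n_coloc, coloc_rate.
#' @export
object_coloc_counts <- function(query_spots, other_mask, cm,
                                min_overlap_px = 1) {
  stopifnot(inherits(query_spots, "spot_set"), inherits(cm, "cell_map"),
            min_overlap_px >= 1)
  if (!all(dim(query_spots$source_mask) == dim(other_mask)))
    stop("mask dimensions differ")
  ids <- retained_cells(cm)
  if (length(ids) == 0)
    return(data.frame(cell_id = integer(0), n_obj = integer(0),
                      n_coloc = integer(0), coloc_rate = numeric(0)))
  coloc_lab <- spot_coloc_flags(query_spots, other_mask, min_overlap_px)
  s <- query_spots$spots
  out <- do.call(rbind, lapply(ids, function(id) {
    k <- which(!is.na(s$cell_id) & s$cell_id == id)
    n <- length(k)
    nc <- sum(coloc_lab[s$label[k]])
    data.frame(cell_id = id, n_obj = n, n_coloc = nc,
               coloc_rate = if (n > 0) nc / n else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Per-object co-localization flags against a partner mask
#'
#' For every object of a `spot_set`, TRUE iff the object shares at least
#' `min_overlap_px` pixels with `other_mask`, evaluated through the
#' AND-gate of the object mask and the partner mask.
#'
#' @param spot_set a `spot_set`.
#' @param other_mask binary mask, same dimensions.
#' @param min_overlap_px minimum shared pixel count.
#' @return logical vector indexed by spot label.
#' @export
spot_coloc_flags <- function(spot_set, other_mask, min_overlap_px = 1) {
  n <- nrow(spot_set$spots)
  if (n == 0) return(logical(0))
  gate <- and_gate(spot_set$source_mask, other_mask)
  ov <- tabulate(spot_set$source_labels[gate], nbins = n)
  ov >= min_overlap_px
}

#' Classify randomly sampled MVEs by co-localized miRNA strand
#'
#' Per retained cell, samples `min(sample_n, n_mve)` MVE objects without
#' replacement from a seeded per-cell stream and classifies each into
#' exactly one of single / guide-only / passenger-only / both by the
#' object-overlap rule against each miRNA mask. Both the exclusive 4-way
#' counts and the inclusive marginal tallies (`n_guide_pos` = guide-only +
#' both, `n_passenger_pos` = passenger-only + both) are reported; the
#' projection convention is recorded in the `projection` attribute.
#'
#' @param mve_spots a `spot_set` of MVE objects with cell assignments.
#' @param guide_mask,passenger_mask binary miRNA masks (same dimensions).
#' @param cm a `cell_map`.
#' @param sample_n MVEs sampled per cell (default 20).
#' @param seed integer seed for the sampling streams.
#' @param min_overlap_px minimum shared pixel count (default 1).
#' @return data.frame with one row per retained cell: cell_id, n_mve,
#'   n_evaluated, n_single, n_guide_only, n_passenger_only, n_both,
#'   n_guide_pos, n_passenger_pos, coloc_rate (any-miRNA fraction of the
#'   evaluated MVEs).
#' @export
classify_mves <- function(mve_spots, guide_mask, passenger_mask, cm,
                          sample_n = 20, seed = 1L, min_overlap_px = 1) {
  stopifnot(sample_n >= 1)
  g_flag <- spot_coloc_flags(mve_spots, guide_mask, min_overlap_px)
  p_flag <- spot_coloc_flags(mve_spots, passenger_mask, min_overlap_px)
  ids <- retained_cells(cm)
  s <- mve_spots$spots
  out <- do.call(rbind, lapply(ids, function(id) {
    k <- which(!is.na(s$cell_id) & s$cell_id == id)
    n_mve <- length(k)
    n_eval <- min(sample_n, n_mve)
    sel <- if (n_eval > 0)
      with_seed(mix_seed(seed, 7L, id), k[sample.int(n_mve, n_eval)])
    else integer(0)
    g <- g_flag[s$label[sel]]; p <- p_flag[s$label[sel]]
    data.frame(
      cell_id = id, n_mve = n_mve, n_evaluated = n_eval,
      n_single = sum(!g & !p),
      n_guide_only = sum(g & !p),
      n_passenger_only = sum(!g & p),
      n_both = sum(g & p),
      n_guide_pos = sum(g),
      n_passenger_pos = sum(p),
      coloc_rate = if (n_eval > 0) sum(g | p) / n_eval else NA_real_
    )
  }))
  if (is.null(out))
    out <- data.frame(cell_id = integer(0), n_mve = integer(0),
                      n_evaluated = integer(0), n_single = integer(0),
                      n_guide_only = integer(0), n_passenger_only = integer(0),
                      n_both = integer(0), n_guide_pos = integer(0),
                      n_passenger_pos = integer(0), coloc_rate = numeric(0))
  rownames(out) <- NULL
  attr(out, "projection") <- "inclusive: n_guide_pos = guide-only + both"
  out
}

#' Nuclear-accumulation scoring per cell
#'
#' A retained cell is scored "accumulated" when the mean miRNA intensity
#' over its nucleus is at least `ratio_threshold` times the mean over its
#' cytoplasm. Cells with zero cytoplasmic mean are skipped with a warning.
#'
#' @param mirna_image 2D matrix of the miRNA channel (projected).
#' @param cm a `cell_map`.
#' @param ratio_threshold nuclear/cytoplasmic mean ratio cutoff
#'   (default 1.5).
#' @return list with `per_cell` (cell_id, nuclear_mean, cytoplasm_mean,
#'   ratio, accumulated) and `fraction_accumulated`.
#' @export
nuclear_accumulation <- function(mirna_image, cm, ratio_threshold = 1.5) {
  stopifnot(ratio_threshold > 0,
            all(dim(mirna_image) == dim(cm$cell_labels)))
  ids <- retained_cells(cm)
  rows <- lapply(ids, function(id) {
    nuc <- mirna_image[cm$nucleus_labels == id]
    cyt <- mirna_image[cytoplasm_region(cm, id)]
    cyt_mean <- mean(cyt)
    if (!length(cyt) || cyt_mean == 0) {
      warning(sprintf("cell %d: zero cytoplasmic mean, skipped", id))
      return(NULL)
    }
    r <- mean(nuc) / cyt_mean
    data.frame(cell_id = id, nuclear_mean = mean(nuc),
               cytoplasm_mean = cyt_mean, ratio = r,
               accumulated = r >= ratio_threshold)
  })
  per_cell <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(per_cell))
    per_cell <- data.frame(cell_id = integer(0), nuclear_mean = numeric(0),
                           cytoplasm_mean = numeric(0), ratio = numeric(0),
                           accumulated = logical(0))
  list(per_cell = per_cell,
       fraction_accumulated =
         if (nrow(per_cell) > 0) mean(per_cell$accumulated) else NA_real_)
}

#' Pixelwise Pearson co-localization coefficient
#'
#' Sample Pearson correlation of two channels over the pixels selected by
#' `mask`.
#'
#' @param image_a,image_b 2D matrices of identical dimensions.
#' @param mask logical matrix selecting >= 2 pixels with nonzero variance
#'   in both channels (defaults to all pixels).
#' @return correlation in \[-1, 1\].
#' @export
pearson_coefficient <- function(image_a, image_b, mask = NULL) {
  if (!all(dim(image_a) == dim(image_b)))
    stop("image dimensions differ")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image_a), ncol(image_a))
  a <- image_a[mask]; b <- image_b[mask]
  if (length(a) < 2) stop("mask must select at least 2 pixels")
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("zero variance in a channel: correlation undefined")
  stats::cor(a, b)
}
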