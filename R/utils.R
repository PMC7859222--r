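# Shared low-level helpers: seed mixing, 8-connected labeling, thresholds,
# ellipse geometry.

# Deterministic 32-bit-safe seed mixer. Splits one user seed into independent
# sub-seeds (stage, cell, ...) without ever exceeding 2^31 - 1, so derived
# seeds remain valid arguments to set.seed().
mix_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (k in ks) {
    # split into 16-bit halves to stay inside exact double arithmetic
    lo <- s %% 65536
    hi <- (s - lo) / 65536
    s <- (lo * 40503 + hi * 30269 + as.double(k) * 7919 + 12345) %% 2147483647
  }
  as.integer(s)
}

# Evaluate RNG-consuming code under a local seed, restoring the caller's RNG
# state afterwards so seeded package functions do not disturb user code.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Label connected components of a binary mask
#'
#' 8-connected (default) or 4-connected component labeling by iterative
#' minimum-label propagation. Labels are consecutive positive integers in
#' raster (column-major) order of each component's first pixel; background
#' is 0.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of the same dimension.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  m <- mask != 0
  lab <- matrix(0, nrow(m), ncol(m))
  if (!any(m)) return(lab)
  lab[m] <- seq_len(sum(m))
  nr <- nrow(m); nc <- ncol(m)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8)
    shifts <- c(shifts, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  repeat {
    new <- lab
    for (s in shifts) {
      sh <- shift_matrix(new, s[1], s[2])
      upd <- m & sh > 0 & (new == 0 | sh < new)
      new[upd] <- sh[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  # relabel consecutively by first occurrence
  ids <- lab[lab > 0]
  u <- unique(ids)
  remap <- integer(max(u))
  remap[u] <- seq_along(u)
  lab[lab > 0] <- remap[ids]
  lab
}

# shift matrix by (dr, dc), padding with 0
shift_matrix <- function(x, dr, dc) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  ok_r <- rs >= 1 & rs <= nr
  ok_c <- cs >= 1 & cs <= nc
  out[which(ok_r), which(ok_c)] <- x[rs[ok_r], cs[ok_c], drop = FALSE]
  out
}

# Threshold a numeric vector of (positive) values. Otsu is delegated to
# EBImage on a normalized single-column image; ties in bin edges resolve
# toward the lower threshold because the mask test uses >=.
threshold_value <- function(values, method = c("otsu", "percentile", "fixed"),
                            fixed = NULL, percentile = 0.99, levels = 256) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(fixed)) stop("threshold method 'fixed' needs a value")
    return(fixed)
  }
  if (method == "percentile")
    return(stats::quantile(values, percentile, names = FALSE))
  rng <- range(values)
  if (diff(rng) <= 0) {
    warning("constant values: threshold undefined, returning +Inf")
    return(Inf)
  }
  img <- EBImage::as.Image(matrix(values, ncol = 1))
  EBImage::otsu(img, range = rng, levels = levels)
}

# point-in-ellipse test; theta in radians, (a, b) semi-axes in px,
# coordinates are (row, col)
inside_ellipse <- function(r, c, cr, cc, a, b, theta) {
  dr <- r - cr; dc <- c - cc
  u <- dc * cos(theta) + dr * sin(theta)
  v <- -dc * sin(theta) + dr * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# rasterize an ellipse into a logical matrix of dim (nr, nc)
ellipse_mask <- function(nr, nc, cr, cc, a, b, theta) {
  rmax <- max(a, b)
  r0 <- max(1L, floor(cr - rmax)); r1 <- min(nr, ceiling(cr + rmax))
  c0 <- max(1L, floor(cc - rmax)); c1 <- min(nc, ceiling(cc + rmax))
  out <- matrix(FALSE, nr, nc)
  if (r0 > r1 || c0 > c1) return(out)
  rs <- r0:r1; cs <- c0:c1
  grid_r <- matrix(rs, length(rs), length(cs))
  grid_c <- matrix(cs, length(rs), length(cs), byrow = TRUE)
  out[rs, cs] <- inside_ellipse(grid_r, grid_c, cr, cc, a, b, theta)
  out
}

# uniform sample of n points inside an ellipse (optionally excluding an
# inner concentric ellipse) by rejection; returns matrix with columns (r, c)
sample_in_ellipse <- function(n, cr, cc, a, b, theta,
                              excl = NULL, max_iter = 10000L) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  pts <- matrix(NA_real_, n, 2)
  got <- 0L
  rmax <- max(a, b)
  for (i in seq_len(max_iter)) {
    need <- n - got
    r <- runif(2 * need + 8, cr - rmax, cr + rmax)
    c <- runif(2 * need + 8, cc - rmax, cc + rmax)
    ok <- inside_ellipse(r, c, cr, cc, a, b, theta)
    if (!is.null(excl))
      ok <- ok & !inside_ellipse(r, c, excl$cr, excl$cc, excl$a, excl$b,
                                 excl$theta)
    k <- which(ok)
    if (length(k) > 0) {
      take <- k[seq_len(min(length(k), need))]
      pts[got + seq_along(take), ] <- cbind(r[take], c[take])
      got <- got + length(take)
    }
    if (got >= n) break
  }
  if (got < n) stop("rejection sampling failed to place points in region")
  pts
}
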