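#' @importFrom rlang abort warn %||%
#' @importFrom stats sd rnorm setNames
#' @importFrom grDevices chull
NULL

# stop with a classed condition so callers/tests can match on class
stop_lvpnt <- function(msg, class) {
  rlang::abort(msg, class = c(class, "lvpnt_error"))
}

assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_lvpnt(sprintf("`%s` must be a single finite number", name), "lvpnt_validation_error")
  }
  if (positive && x <= 0) {
    stop_lvpnt(sprintf("`%s` must be > 0 (got %g)", name, x), "lvpnt_validation_error")
  }
  if (nonneg && x < 0) {
    stop_lvpnt(sprintf("`%s` must be >= 0 (got %g)", name, x), "lvpnt_validation_error")
  }
  invisible(x)
}

# binary matrix helpers -------------------------------------------------------

as_mask <- function(m) {
  storage.mode(m) <- "integer"
  m
}

#' Disc-shaped structuring element
#'
#' @param diameter_px structuring-element diameter in pixels.
#' @return a 0/1 matrix usable as an `EBImage` brush, or `NULL` when the
#'   diameter does not exceed one pixel (morphology would be a no-op).
#' @keywords internal
disc_brush <- function(diameter_px) {
  d <- as.integer(round(diameter_px))
  if (d <= 1L) return(NULL)
  if (d == 2L) return(matrix(1L, 2L, 2L))
  if (d %% 2L == 0L) d <- d - 1L  # EBImage disc brushes are odd-sized
  if (d < 3L) return(matrix(1L, 2L, 2L))
  EBImage::makeBrush(d, shape = "disc")
}

mask_open <- function(mask, brush) {
  if (is.null(brush) || !any(mask)) return(as_mask(mask))
  as_mask(EBImage::opening(mask, brush) > 0)
}

mask_close <- function(mask, brush) {
  if (is.null(brush) || !any(mask)) return(as_mask(mask))
  as_mask(EBImage::closing(mask, brush) > 0)
}

# largest 4/8-connected component of a binary matrix (empty input -> empty)
largest_component <- function(mask) {
  if (!any(mask)) return(as_mask(mask * 0L))
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(lab[lab > 0])
  as_mask(lab == which.max(tab))
}

fill_holes <- function(mask) {
  if (!any(mask)) return(as_mask(mask))
  as_mask(EBImage::fillHull(mask) > 0)
}

# Rasterized convex hull of a binary mask, optionally offset outwards by a
# sub-pixel margin (in pixels). Pixels are tested against the hull polygon
# (grDevices::chull) by signed cross products, vectorized over the image.
convex_hull_mask <- function(mask, offset = 0) {
  if (!any(mask > 0)) return(as_mask(mask * 0L))
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) < 3L) return(as_mask(mask > 0))
  h <- grDevices::chull(idx[, 1], idx[, 2])
  vx <- idx[h, 1]; vy <- idx[h, 2]          # chull returns clockwise order
  d <- dim(mask)
  px <- rep(seq_len(d[1]), times = d[2])
  py <- rep(seq_len(d[2]), each = d[1])
  inside <- rep(TRUE, length(px))
  nv <- length(vx)
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    ex <- vx[j] - vx[i]; ey <- vy[j] - vy[i]
    len <- sqrt(ex * ex + ey * ey)
    if (len == 0) next
    cross <- ex * (py - vy[i]) - ey * (px - vx[i])
    inside <- inside & (cross <= offset * len)
    if (!any(inside)) break
  }
  as_mask(matrix(inside, d[1], d[2]))
}

# Dice coefficient between two binary masks/arrays
dice <- function(a, b) {
  a <- a > 0; b <- b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# deterministic per-subject seed derivation, kept below .Machine$integer.max
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 48271 + index * 16807) %% 2147483647)
}
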