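#' Segmentation configuration
#'
#' Tunable parameters of the dual-convention segmentation. The two numeric
#' rules taken from the contouring protocol are the intensity band
#' (papillary/trabecular tissue has signal within `intensity_band_sd` standard
#' deviations of the free-wall myocardial signal) and the minimum trabecular
#' width (`min_trabecula_width`, structures strictly below it are returned to
#' the blood pool). Everything else is a documented default of this
#' implementation.
#'
#' @param intensity_band_sd half-width of the inclusive intensity band, in
#'   multiples of the free-wall standard deviation. Default 1.
#' @param min_trabecula_width minimum in-plane width (mm) of a papillary or
#'   trabecular structure retained in the myocardium; strictly thinner
#'   connected components are discarded. Default 1.5 mm.
#' @param smooth_closing_radius radius (mm) of the morphological closing disc
#'   used to draw the smooth compacted-myocardium endocardial contour.
#' @param freewall_roi_policy free-wall reference ROI policy; currently
#'   `"lateral_sector"`: a 120 degree mid-wall sector centred on
#'   `freewall_angle`.
#' @param freewall_angle centre (degrees) of the free-wall sector.
#' @param basal_enclosure_threshold minimum fraction of the cavity boundary
#'   that must touch myocardium for a slice to qualify as basal.
#' @param wall_depth_quantile quantile of the epicardial depth of
#'   wall-adjacent blood pixels used to estimate the compact wall thickness;
#'   0 (the default) uses the minimum, which is bounded below by the true
#'   thickness and stable with and without noise.
#' @param wall_depth_margin_px additive margin (pixels) on the estimated wall
#'   thickness before the smooth endocardial region is cut.
#' @param hull_offset_px outward sub-pixel offset (in pixels) applied to the
#'   convex-hull estimate of the smooth endocardial region (the fallback used
#'   on slices with too little wall-adjacent blood), compensating the inward
#'   partial-volume bias of the hull vertices.
#' @param median_filter_size half-size (pixels) of the median pre-filter
#'   applied before classification; 0 disables it.
#' @param min_contrast_separation minimum acceptable separation (in pooled
#'   within-class standard deviations) between the blood and myocardium
#'   intensity classes; below it segmentation aborts with a diagnostic.
#' @return an object of class `segmentation_config`.
#' @export
segmentation_config <- function(intensity_band_sd = 1.0,
                                min_trabecula_width = 1.5,
                                smooth_closing_radius = 5,
                                freewall_roi_policy = "lateral_sector",
                                freewall_angle = 0,
                                basal_enclosure_threshold = 0.5,
                                wall_depth_quantile = 0,
                                wall_depth_margin_px = 0,
                                hull_offset_px = 0.5,
                                median_filter_size = 0L,
                                min_contrast_separation = 3) {
  assert_scalar_num(intensity_band_sd, "intensity_band_sd", positive = TRUE)
  assert_scalar_num(min_trabecula_width, "min_trabecula_width", nonneg = TRUE)
  assert_scalar_num(smooth_closing_radius, "smooth_closing_radius", nonneg = TRUE)
  if (!(basal_enclosure_threshold > 0 && basal_enclosure_threshold <= 1)) {
    stop_lvpnt("`basal_enclosure_threshold` must lie in (0, 1]", "lvpnt_validation_error")
  }
  freewall_roi_policy <- match.arg(freewall_roi_policy, "lateral_sector")
  structure(list(
    intensity_band_sd = intensity_band_sd,
    min_trabecula_width = min_trabecula_width,
    smooth_closing_radius = smooth_closing_radius,
    freewall_roi_policy = freewall_roi_policy,
    freewall_angle = freewall_angle,
    basal_enclosure_threshold = basal_enclosure_threshold,
    wall_depth_quantile = wall_depth_quantile,
    wall_depth_margin_px = wall_depth_margin_px,
    hull_offset_px = hull_offset_px,
    median_filter_size = as.integer(median_filter_size),
    min_contrast_separation = min_contrast_separation
  ), class = "segmentation_config")
}

#' Locate end-diastole and end-systole on a cavity volume curve
#'
#' End-diastole is the phase with the largest cavity volume and end-systole
#' the phase with the smallest; ties are broken towards the earliest phase.
#'
#' @param cavity_volume_curve numeric vector of cavity volumes (ml), one per
#'   cardiac phase.
#' @return a list with integer elements `ed` and `es` (1-based phase indices).
#' @export
#' @examples
#' find_ed_es_phases(c(100, 80, 60, 80))  # ed = 1, es = 3
find_ed_es_phases <- function(cavity_volume_curve) {
  v <- cavity_volume_curve
  if (length(v) < 2L || !is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
    stop_lvpnt("cavity volume curve must be >= 2 finite values", "lvpnt_validation_error")
  }
  list(ed = which.max(v), es = which.min(v))
}

#' Free-wall myocardial reference statistics
#'
#' Returns the sample mean and sample standard deviation (n - 1 denominator)
#' of the image intensities in a free-wall region of interest: by default the
#' lateral 120 degree mid-wall sector of the supplied compact-wall mask
#' (the wall eroded by one pixel, restricted to the sector centred on
#' `config$freewall_angle`).
#'
#' @param slice_image 2D intensity matrix (a.u.).
#' @param compact_wall_mask binary matrix marking the compact myocardial wall.
#' @param config a [segmentation_config()].
#' @return a list with elements `mean`, `sd` and `n` (ROI pixel count).
#' @export
freewall_reference_stats <- function(slice_image, compact_wall_mask,
                                     config = segmentation_config()) {
  if (!all(dim(slice_image) == dim(compact_wall_mask))) {
    stop_lvpnt("image and wall mask shapes differ", "lvpnt_validation_error")
  }
  if (!any(compact_wall_mask > 0)) {
    stop_lvpnt("empty compact-wall mask: no free-wall ROI", "lvpnt_segmentation_error")
  }
  roi <- freewall_roi(compact_wall_mask, config)
  if (!any(roi > 0)) {
    stop_lvpnt("free-wall ROI is empty under the configured sector",
               "lvpnt_segmentation_error")
  }
  vals <- slice_image[roi > 0]
  list(mean = mean(vals), sd = if (length(vals) > 1L) stats::sd(vals) else 0,
       n = length(vals))
}

# sector + mid-wall erosion ROI; falls back to the uneroded wall sector, then
# to the full wall, so a thin wall never yields an empty ROI by accident
freewall_roi <- function(compact_wall_mask, config) {
  d <- dim(compact_wall_mask)
  idx <- which(compact_wall_mask > 0, arr.ind = TRUE)
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  row_g <- matrix(seq_len(d[1]), d[1], d[2]) - cx
  col_g <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - cy
  ang <- atan2(col_g, row_g) * 180 / pi
  delta <- (ang - config$freewall_angle + 180) %% 360 - 180
  sector <- abs(delta) <= 60
  eroded <- EBImage::erode(compact_wall_mask, EBImage::makeBrush(3, "box")) > 0
  roi <- eroded & sector
  if (!any(roi)) roi <- (compact_wall_mask > 0) & sector
  if (!any(roi)) roi <- compact_wall_mask > 0
  as_mask(roi)
}

#' Classify papillary/trabecular pixels by the intensity-band rule
#'
#' A pixel inside the cavity region is classified as papillary or trabecular
#' tissue when its intensity lies within `intensity_band_sd` standard
#' deviations of the free-wall myocardial mean (inclusive band; with a zero
#' standard deviation the band degenerates to exact equality).
#'
#' @param slice_image 2D intensity matrix (a.u.).
#' @param cavity_region binary matrix delimiting the candidate cavity region.
#' @param mean,sd free-wall reference statistics (a.u.), e.g. from
#'   [freewall_reference_stats()].
#' @param config a [segmentation_config()].
#' @return binary matrix of papillary/trabecular pixels.
#' @export
classify_pnt <- function(slice_image, cavity_region, mean, sd,
                         config = segmentation_config()) {
  if (!all(dim(slice_image) == dim(cavity_region))) {
    stop_lvpnt("image and cavity mask shapes differ", "lvpnt_validation_error")
  }
  assert_scalar_num(sd, "sd", nonneg = TRUE)
  band <- config$intensity_band_sd * sd
  as_mask((cavity_region > 0) & (abs(slice_image - mean) <= band))
}

#' Remove trabeculae thinner than the minimum width
#'
#' Discards connected components of the papillary/trabecular mask whose
#' in-plane width is strictly below `min_trabecula_width`. Width is
#' operationalized as survival of a morphological opening with a disc of
#' diameter `min_trabecula_width` (rounded to the nearest whole pixel): a
#' component is kept if and only if any of it survives the opening, so
#' components exactly at the threshold width are retained. When the rounded
#' threshold does not exceed one pixel the filter is a no-op: at such coarse
#' spacing nothing below the threshold is resolvable.
#'
#' @param pnt_mask binary papillary/trabecular mask.
#' @param pixel_spacing in-plane pixel spacing, mm.
#' @param config a [segmentation_config()].
#' @return the filtered binary mask (a subset of the input).
#' @export
filter_thin_trabeculae <- function(pnt_mask, pixel_spacing,
                                   config = segmentation_config()) {
  assert_scalar_num(pixel_spacing, "pixel_spacing", positive = TRUE)
  if (!any(pnt_mask > 0)) return(as_mask(pnt_mask * 0L))
  d_px <- round(config$min_trabecula_width / pixel_spacing)
  if (d_px <= 1) return(as_mask(pnt_mask > 0))
  brush <- disc_brush(d_px)
  opened <- mask_open(pnt_mask > 0, brush)
  lab <- EBImage::bwlabel(pnt_mask > 0)
  keep <- setdiff(unique(lab[opened > 0]), 0)
  as_mask(matrix(lab %in% keep, nrow(lab), ncol(lab)))
}

#' Smooth compacted-myocardium endocardial contour
#'
#' Draws the endocardial border as a smooth path along the compacted
#' myocardium: papillary muscles and trabeculations are returned to the blood
#' pool. The region enclosed by the compact wall is united with the
#' papillary/trabecular mask, closed with a disc of radius
#' `smooth_closing_radius`, and the largest connected component is returned.
#' The result is a superset of the blood-only cavity.
#'
#' @param compact_wall_mask binary compact-wall mask.
#' @param pnt_mask binary papillary/trabecular mask.
#' @param config a [segmentation_config()].
#' @param pixel_spacing in-plane pixel spacing, mm.
#' @return binary cavity mask under the excluding convention.
#' @export
smooth_endocardial_contour <- function(compact_wall_mask, pnt_mask,
                                       config = segmentation_config(),
                                       pixel_spacing = 1) {
  if (!all(dim(compact_wall_mask) == dim(pnt_mask))) {
    stop_lvpnt("mask shapes differ", "lvpnt_validation_error")
  }
  interior <- fill_holes(compact_wall_mask > 0) & !(compact_wall_mask > 0)
  region <- interior | (pnt_mask > 0)
  if (!any(region)) {
    stop_lvpnt("no cavity enclosed by the compact wall", "lvpnt_segmentation_error")
  }
  brush <- disc_brush(2 * config$smooth_closing_radius / pixel_spacing)
  largest_component(mask_close(region, brush))
}

#' Select the basal and apical slices
#'
#' The basal slice is the first slice (counting from the base) in which at
#' least `basal_enclosure_threshold` of the cavity boundary is adjacent to
#' myocardium; the apical slice is the last slice showing intracavity blood
#' pool. Slices outside the returned range are excluded from quantification.
#'
#' @param cavity_masks list of per-slice binary cavity masks at end-diastole
#'   (most basal slice first).
#' @param wall_masks list of matching per-slice compact-wall masks.
#' @param config a [segmentation_config()].
#' @return list with integer elements `basal` and `apical`.
#' @export
select_slices <- function(cavity_masks, wall_masks,
                          config = segmentation_config()) {
  n <- length(cavity_masks)
  if (n < 1L || length(wall_masks) != n) {
    stop_lvpnt("need matching non-empty per-slice mask lists", "lvpnt_validation_error")
  }
  enclosure <- vapply(seq_len(n), function(k) {
    slice_enclosure_fraction(cavity_masks[[k]], wall_masks[[k]])
  }, numeric(1))
  nonempty <- vapply(cavity_masks, function(m) any(m > 0), logical(1))
  basal_ok <- which(nonempty & enclosure >= config$basal_enclosure_threshold)
  if (length(basal_ok) == 0L) {
    stop_lvpnt("no slice satisfies the basal enclosure criterion",
               "lvpnt_segmentation_error")
  }
  basal <- basal_ok[1L]
  apical <- max(which(nonempty))
  list(basal = basal, apical = apical, enclosure = enclosure)
}

# Fraction of cavity-boundary pixels whose neighbourhood contains myocardium.
# The wall mask is opened first so that hairline partial-volume rims (one
# pixel wide) do not count as enclosing myocardium.
slice_enclosure_fraction <- function(cavity_mask, wall_mask, min_wall_px = 3) {
  if (!any(cavity_mask > 0)) return(0)
  m <- cavity_mask > 0
  boundary <- m & !(EBImage::erode(m, EBImage::makeBrush(3, "box")) > 0)
  if (!any(boundary)) boundary <- m
  wall_solid <- mask_open(wall_mask > 0, disc_brush(min_wall_px))
  if (!any(wall_solid > 0)) return(0)
  near_wall <- EBImage::dilate(wall_solid > 0, EBImage::makeBrush(5, "box")) > 0
  sum(boundary & near_wall) / sum(boundary)
}
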