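#' Quantification configuration
#'
#' @param myocardial_density myocardial tissue density, g/ml. Default 1.05,
#'   the conventional value used to convert myocardial volume to mass.
#' @param bsa_formula body-surface-area formula; currently `"mosteller"`.
#' @return an object of class `quant_config`.
#' @export
quant_config <- function(myocardial_density = 1.05, bsa_formula = "mosteller") {
  assert_scalar_num(myocardial_density, "myocardial_density", positive = TRUE)
  bsa_formula <- match.arg(bsa_formula, "mosteller")
  structure(list(myocardial_density = myocardial_density,
                 bsa_formula = bsa_formula), class = "quant_config")
}

#' Slice-summation (Simpson) volume
#'
#' Sums per-slice cross-sectional areas times the effective slice spacing
#' (slice thickness plus inter-slice gap).
#'
#' @param areas numeric vector of per-slice areas, mm^2.
#' @param slice_thickness slice thickness, mm.
#' @param slice_gap inter-slice gap, mm.
#' @return volume in ml.
#' @export
#' @examples
#' slice_summation_volume(100, 8, 2)  # 1 ml
slice_summation_volume <- function(areas, slice_thickness, slice_gap = 0) {
  assert_scalar_num(slice_thickness, "slice_thickness", positive = TRUE)
  assert_scalar_num(slice_gap, "slice_gap", nonneg = TRUE)
  if (length(areas) == 0L) return(0)
  if (any(!is.finite(areas)) || any(areas < 0)) {
    stop_lvpnt("slice areas must be finite and non-negative", "lvpnt_validation_error")
  }
  sum(areas) * (slice_thickness + slice_gap) / 1000
}

#' Myocardial mass from myocardial volume
#'
#' @param myocardial_volume myocardial volume, ml.
#' @param config a [quant_config()].
#' @return mass in g.
#' @export
myocardial_mass <- function(myocardial_volume, config = quant_config()) {
  assert_scalar_num(myocardial_volume, "myocardial_volume", nonneg = TRUE)
  myocardial_volume * config$myocardial_density
}

#' Ejection fraction from end-diastolic and end-systolic volumes
#'
#' @param edv,esv end-diastolic and end-systolic volumes, ml.
#' @return ejection fraction in percent: `100 * (edv - esv) / edv`.
#' @export
#' @examples
#' ejection_fraction(163, 54)
ejection_fraction <- function(edv, esv) {
  if (any(edv <= 0)) stop_lvpnt("end-diastolic volume must be > 0", "lvpnt_validation_error")
  100 * (edv - esv) / edv
}

#' Papillary/trabecular mass fraction
#'
#' Percentage of total left-ventricular mass attributable to papillary
#' muscles and trabeculations, from the mass measured with the structures
#' included versus excluded.
#'
#' @param lvm_inc LV mass including papillary/trabecular tissue, g.
#' @param lvm_ex LV mass excluding it (compact wall only), g.
#' @return fraction in percent: `100 * (lvm_inc - lvm_ex) / lvm_inc`.
#' @export
#' @examples
#' pnt_fraction(130, 113)
pnt_fraction <- function(lvm_inc, lvm_ex) {
  if (any(lvm_ex <= 0) || any(lvm_inc <= 0)) {
    stop_lvpnt("masses must be positive", "lvpnt_validation_error")
  }
  if (any(lvm_ex > lvm_inc + 1e-9)) {
    stop_lvpnt("mass excluding P&T cannot exceed mass including P&T",
               "lvpnt_validation_error")
  }
  100 * (lvm_inc - lvm_ex) / lvm_inc
}

#' Body surface area
#'
#' Mosteller formula: `sqrt(height_cm * weight_kg / 3600)`.
#'
#' @param height height, cm.
#' @param weight weight, kg.
#' @param config a [quant_config()].
#' @return body surface area, m^2.
#' @export
body_surface_area <- function(height, weight, config = quant_config()) {
  assert_scalar_num(height, "height", positive = TRUE)
  assert_scalar_num(weight, "weight", positive = TRUE)
  sqrt(height * weight / 3600)
}

slice_range_areas <- function(mask_arr, basal, apical, px) {
  vapply(basal:apical, function(k) sum(mask_arr[k, , ] > 0) * px * px, numeric(1))
}

#' Ventricular measures for one contouring convention
#'
#' Turns a segmentation into the standard left-ventricular measures for the
#' chosen endocardial convention. Under `"minc"` (papillary muscles and
#' trabeculations included in the myocardium) the cavity is the blood-only
#' region and the end-diastolic myocardium is wall plus papillary/trabecular
#' tissue; under `"mex"` the cavity is bounded by the smooth
#' compacted-myocardium contour and the myocardium is the compact wall only.
#' Mass is measured at end-diastole. Volumes use slice summation over the
#' selected basal-to-apical range.
#'
#' @param seg an `lv_segmentation` from [segment_subject()].
#' @param method `"minc"` or `"mex"`.
#' @param config a [quant_config()].
#' @param bsa optional body surface area (m^2) for indexed mass.
#' @return a one-row tibble with `method`, `lvedv`, `lvesv`, `lvsv` (ml),
#'   `lvef` (%), `lvm` (g), `lvm_indexed` (g/m^2, `NA` without `bsa`),
#'   `pnt_mass` (g; 0 by construction for `"mex"`) and `pnt_volume_ed` (ml).
#' @export
ventricular_measures <- function(seg, method = c("minc", "mex"),
                                 config = quant_config(), bsa = NULL) {
  if (!inherits(seg, "lv_segmentation")) {
    stop_lvpnt("`seg` must come from segment_subject()", "lvpnt_validation_error")
  }
  method <- match.arg(method)
  px <- seg$pixel_spacing
  b <- seg$basal_slice; a <- seg$apical_slice
  cav <- if (method == "minc") "minc_cavity" else "mex_cavity"
  edv <- slice_summation_volume(slice_range_areas(seg$ed[[cav]], b, a, px),
                                seg$slice_thickness, seg$slice_gap)
  esv <- slice_summation_volume(slice_range_areas(seg$es[[cav]], b, a, px),
                                seg$slice_thickness, seg$slice_gap)
  if (edv <= 0) stop_lvpnt("empty end-diastolic cavity", "lvpnt_segmentation_error")

  # mass is traced base to apex: beyond the last blood-pool slice the apical
  # cap still carries myocardium, so the mass summation extends to the last
  # slice with epicardium
  epi_per_slice <- vapply(seq_len(dim(seg$ed$epi)[1]),
                          function(k) sum(seg$ed$epi[k, , ] > 0), numeric(1))
  a_mass <- max(c(a, which(epi_per_slice > 0)))
  epi_v <- slice_summation_volume(slice_range_areas(seg$ed$epi, b, a_mass, px),
                                  seg$slice_thickness, seg$slice_gap)
  myo_v <- epi_v - edv_for_mass(seg, method, b, a_mass, px)
  lvm <- myocardial_mass(max(myo_v, 0), config)
  pnt_v <- slice_summation_volume(slice_range_areas(seg$ed$pnt, b, a, px),
                                  seg$slice_thickness, seg$slice_gap)
  tibble::tibble(
    method = method,
    lvedv = edv,
    lvesv = esv,
    lvsv = edv - esv,
    lvef = ejection_fraction(edv, esv),
    lvm = lvm,
    lvm_indexed = if (is.null(bsa)) NA_real_ else lvm / bsa,
    pnt_mass = if (method == "minc") myocardial_mass(pnt_v, config) else 0,
    pnt_volume_ed = if (method == "minc") pnt_v else 0
  )
}

# cavity volume entering the mass computation: the myocardium is everything
# inside the epicardium that is not cavity under the given convention
edv_for_mass <- function(seg, method, b, a, px) {
  cav <- if (method == "minc") "minc_cavity" else "mex_cavity"
  slice_summation_volume(slice_range_areas(seg$ed[[cav]], b, a, px),
                         seg$slice_thickness, seg$slice_gap)
}

#' Measure one subject with both conventions
#'
#' Convenience wrapper: segments the subject's cine stack, quantifies both
#' conventions, and integrates the aortic velocity series.
#'
#' @param subject a `subject_record` from [generate_cohort()], or an
#'   `lv_phantom`.
#' @param seg_config a [segmentation_config()].
#' @param quant a [quant_config()].
#' @return a two-row tibble (one row per method) with the ventricular
#'   measures, `aortic_sv` (ml), the papillary/trabecular mass fraction
#'   `pnt_fraction_pct` (on the `minc` row), and subject metadata when
#'   available.
#' @export
measure_subject <- function(subject, seg_config = segmentation_config(),
                            quant = quant_config()) {
  cine <- subject$cine
  seg <- segment_subject(cine, seg_config)
  bsa <- if (!is.null(subject$height)) {
    body_surface_area(subject$height, subject$weight, quant)
  } else NULL
  m <- dplyr::bind_rows(
    ventricular_measures(seg, "minc", quant, bsa),
    ventricular_measures(seg, "mex", quant, bsa)
  )
  lvm_inc <- m$lvm[m$method == "minc"]
  lvm_ex <- m$lvm[m$method == "mex"]
  m$pnt_fraction_pct <- ifelse(
    m$method == "minc" & lvm_inc >= lvm_ex & lvm_ex > 0,
    pnt_fraction(max(lvm_inc, lvm_ex), min(lvm_inc, lvm_ex)), NA_real_)
  if (!is.null(subject$velocity)) {
    roi <- detect_vessel_roi(subject$velocity)
    m$aortic_sv <- integrate_flow(subject$velocity, roi)$aortic_sv
  }
  if (!is.null(subject$subject_id)) {
    m <- dplyr::mutate(m,
                       subject_id = subject$subject_id,
                       group = subject$group %||% NA_character_,
                       .before = 1)
  }
  m
}

#' Measure a cohort of subjects
#'
#' @param subjects list of `subject_record`s (see [generate_cohort()]).
#' @param seg_config a [segmentation_config()].
#' @param quant a [quant_config()].
#' @return a tibble with two rows (methods `minc`, `mex`) per subject.
#' @export
measure_cohort <- function(subjects, seg_config = segmentation_config(),
                           quant = quant_config()) {
  purrr::map_dfr(subjects, measure_subject,
                 seg_config = seg_config, quant = quant)
}
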