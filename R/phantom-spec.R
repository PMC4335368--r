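#' Parameter set for a single left-ventricular cine phantom
#'
#' Describes the geometry, motion, tissue contrast and imaging parameters of a
#' digital short-axis cine phantom. The cavity is a truncated half-ellipsoid
#' (base at z = 0, apex at z = `long_axis_length`), the compact wall a
#' concentric shell, papillary muscles are cylinders attached near the
#' mid-cavity wall, and trabeculations are sinusoidal radial ridges on the
#' endocardial surface whose amplitude interpolates from the end-diastolic to
#' the end-systolic value through the cycle (systolic compaction).
#'
#' @param long_axis_length cavity long-axis length (base to apex), mm.
#' @param cavity_semiaxes_ed in-plane semi-axes (a, b) of the smooth
#'   (compacted-myocardium) endocardial surface at end-diastole, mm.
#' @param wall_thickness_ed,wall_thickness_es compact wall thickness at
#'   end-diastole / end-systole, mm.
#' @param ejection_fraction_true fraction (0-1) by which the smooth
#'   endocardial cavity volume contracts from end-diastole to end-systole.
#' @param papillary_count number of papillary muscles (cylinders).
#' @param papillary_radius,papillary_length papillary cylinder radius and
#'   length, mm.
#' @param trabecular_amplitude_ed,trabecular_amplitude_es peak radial depth of
#'   the trabecular ridges at end-diastole / end-systole, mm. The end-systolic
#'   value may not exceed the end-diastolic one (compaction).
#' @param trabecular_angular_frequency number of trabecular ridges per
#'   revolution.
#' @param trabecular_sharpness exponent applied to the (unit-amplitude)
#'   sinusoidal ridge and long-axis taper profiles; values below 1 steepen
#'   the ridge flanks towards a finger-like cross-section.
#' @param trabecular_min_depth minimum ridge depth, mm: where the ridge
#'   field is shallower than this no trabecular tissue exists, so ridges are
#'   discrete structures with stepped edges instead of infinitesimally thin
#'   wings that no imaging protocol could resolve.
#' @param n_phases number of cardiac phases (>= 2).
#' @param rr_interval cardiac cycle length, ms.
#' @param pixel_spacing in-plane pixel spacing, mm.
#' @param slice_thickness,slice_gap slice thickness and inter-slice gap, mm.
#' @param blood_intensity,myocardium_intensity,background_intensity signal
#'   intensities (a.u.) of blood, myocardium (wall, papillary and trabecular
#'   tissue) and background. bSSFP-like contrast requires
#'   `blood_intensity > myocardium_intensity`.
#' @param noise_sd standard deviation of additive Gaussian image noise, a.u.
#' @param supersampling_factor sub-voxel sampling factor per axis used for
#'   partial-volume rendering and ground-truth integration.
#' @param vessel_radius ascending-aorta radius for the velocity series, mm.
#' @param trabecular_phase rotation (radians) of the trabecular ridge pattern.
#' @param basal_slab_length length of the blood-only slab simulated above the
#'   base (atrium/outflow-like, no surrounding myocardium), mm. Exercises the
#'   basal slice-selection rule.
#'
#' @return an object of class `phantom_spec` (a validated named list).
#' @export
#' @examples
#' spec <- phantom_spec(cavity_semiaxes_ed = c(20, 20), long_axis_length = 80,
#'                      papillary_count = 0, trabecular_amplitude_ed = 0,
#'                      trabecular_amplitude_es = 0, noise_sd = 0)
phantom_spec <- function(long_axis_length = 90,
                         cavity_semiaxes_ed = c(29, 29),
                         wall_thickness_ed = 9,
                         wall_thickness_es = 12,
                         ejection_fraction_true = 0.65,
                         papillary_count = 2L,
                         papillary_radius = 7,
                         papillary_length = 40,
                         trabecular_amplitude_ed = 4,
                         trabecular_amplitude_es = 3.2,
                         trabecular_angular_frequency = 12,
                         trabecular_sharpness = 1,
                         trabecular_min_depth = 1.6,
                         n_phases = 20L,
                         rr_interval = 1000,
                         pixel_spacing = 1.4,
                         slice_thickness = 8,
                         slice_gap = 2,
                         blood_intensity = 500,
                         myocardium_intensity = 200,
                         background_intensity = 20,
                         noise_sd = 12,
                         supersampling_factor = 2L,
                         vessel_radius = 14,
                         trabecular_phase = 0,
                         basal_slab_length = 10) {
  spec <- list(
    long_axis_length = long_axis_length,
    cavity_semiaxes_ed = as.numeric(cavity_semiaxes_ed),
    wall_thickness_ed = wall_thickness_ed,
    wall_thickness_es = wall_thickness_es,
    ejection_fraction_true = ejection_fraction_true,
    papillary_count = as.integer(papillary_count),
    papillary_radius = papillary_radius,
    papillary_length = papillary_length,
    trabecular_amplitude_ed = trabecular_amplitude_ed,
    trabecular_amplitude_es = trabecular_amplitude_es,
    trabecular_angular_frequency = trabecular_angular_frequency,
    trabecular_sharpness = trabecular_sharpness,
    trabecular_min_depth = trabecular_min_depth,
    n_phases = as.integer(n_phases),
    rr_interval = rr_interval,
    pixel_spacing = pixel_spacing,
    slice_thickness = slice_thickness,
    slice_gap = slice_gap,
    blood_intensity = blood_intensity,
    myocardium_intensity = myocardium_intensity,
    background_intensity = background_intensity,
    noise_sd = noise_sd,
    supersampling_factor = as.integer(supersampling_factor),
    vessel_radius = vessel_radius,
    trabecular_phase = trabecular_phase,
    basal_slab_length = basal_slab_length
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
}

#' Validate a phantom specification
#'
#' Checks the geometric and imaging invariants of a [phantom_spec()]:
#' positive lengths, ejection fraction strictly inside (0, 1), trabecular
#' compaction (`trabecular_amplitude_es <= trabecular_amplitude_ed`),
#' `n_phases >= 2`, and bright-blood contrast.
#'
#' @param spec a `phantom_spec`.
#' @return the spec, invisibly unchanged, or an error of class
#'   `lvpnt_validation_error`.
#' @export
validate_phantom_spec <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    stop_lvpnt("`spec` must be created with phantom_spec()", "lvpnt_validation_error")
  }
  for (f in c("long_axis_length", "wall_thickness_ed", "wall_thickness_es",
              "pixel_spacing", "slice_thickness", "blood_intensity",
              "myocardium_intensity", "rr_interval", "vessel_radius")) {
    assert_scalar_num(spec[[f]], f, positive = TRUE)
  }
  assert_scalar_num(spec$trabecular_sharpness, "trabecular_sharpness", positive = TRUE)
  for (f in c("papillary_radius", "papillary_length", "trabecular_amplitude_ed",
              "trabecular_amplitude_es", "noise_sd", "slice_gap", "trabecular_min_depth",
              "background_intensity", "basal_slab_length")) {
    assert_scalar_num(spec[[f]], f, nonneg = TRUE)
  }
  if (length(spec$cavity_semiaxes_ed) != 2L || any(spec$cavity_semiaxes_ed <= 0)) {
    stop_lvpnt("`cavity_semiaxes_ed` must be two positive semi-axes (mm)",
               "lvpnt_validation_error")
  }
  ef <- spec$ejection_fraction_true
  if (!is.numeric(ef) || length(ef) != 1L || !is.finite(ef) || ef <= 0 || ef >= 1) {
    stop_lvpnt("`ejection_fraction_true` must lie strictly between 0 and 1",
               "lvpnt_validation_error")
  }
  if (spec$trabecular_amplitude_es > spec$trabecular_amplitude_ed + 1e-9) {
    stop_lvpnt("compaction requires trabecular_amplitude_es <= trabecular_amplitude_ed",
               "lvpnt_validation_error")
  }
  if (spec$n_phases < 2L) {
    stop_lvpnt("`n_phases` must be at least 2", "lvpnt_validation_error")
  }
  if (spec$blood_intensity <= spec$myocardium_intensity) {
    stop_lvpnt("bright-blood contrast requires blood_intensity > myocardium_intensity",
               "lvpnt_validation_error")
  }
  if (spec$papillary_count < 0L) {
    stop_lvpnt("`papillary_count` must be >= 0", "lvpnt_validation_error")
  }
  if (spec$supersampling_factor < 1L) {
    stop_lvpnt("`supersampling_factor` must be >= 1", "lvpnt_validation_error")
  }
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec>\n")
  cat(sprintf("  cavity: half-ellipsoid a=%.1f b=%.1f c=%.1f mm, EF(smooth)=%.2f\n",
              x$cavity_semiaxes_ed[1], x$cavity_semiaxes_ed[2],
              x$long_axis_length, x$ejection_fraction_true))
  cat(sprintf("  wall: %.1f -> %.1f mm; papillary: %d x (r=%.1f, L=%.1f) mm\n",
              x$wall_thickness_ed, x$wall_thickness_es, x$papillary_count,
              x$papillary_radius, x$papillary_length))
  cat(sprintf("  trabeculae: amplitude %.1f -> %.1f mm, %g ridges/rev\n",
              x$trabecular_amplitude_ed, x$trabecular_amplitude_es,
              x$trabecular_angular_frequency))
  cat(sprintf("  imaging: %d phases, %.1f mm px, %g+%g mm slices, noise sd %g a.u.\n",
              x$n_phases, x$pixel_spacing, x$slice_thickness, x$slice_gap,
              x$noise_sd))
  invisible(x)
}
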