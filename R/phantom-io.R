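# NIfTI / JSON / CSV export of simulated subjects.

#' Write a simulated subject to disk
#'
#' Writes the cine stack and ground-truth label masks as 4D NIfTI (x, y,
#' slice, phase), the velocity series as 3D+time NIfTI, and the ground-truth
#' summary as JSON.
#'
#' @param subject a `subject_record` (or `lv_phantom`).
#' @param dir output directory (created if missing).
#' @param id file-name stem; defaults to the subject id.
#' @return invisibly, the named vector of files written.
#' @export
write_subject_nifti <- function(subject, dir, id = NULL) {
  id <- id %||% subject$subject_id %||% "subject"
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cine <- subject$cine
  vel <- subject$velocity
  truth <- subject$truth
  dt_s <- cine$phase_duration / 1000
  dz <- cine$slice_thickness + cine$slice_gap

  to_xyzt <- function(arr4) aperm(arr4, c(3, 4, 2, 1))  # [phase,slice,r,c] -> [x,y,z,t]
  paths <- c(
    cine = file.path(dir, paste0(id, "_cine.nii.gz")),
    labels = file.path(dir, paste0(id, "_labels.nii.gz")),
    velocity = file.path(dir, paste0(id, "_velocity.nii.gz")),
    truth = file.path(dir, paste0(id, "_truth.json"))
  )
  img <- RNifti::asNifti(to_xyzt(cine$intensities))
  RNifti::pixdim(img) <- c(cine$pixel_spacing, cine$pixel_spacing, dz, dt_s)
  RNifti::writeNifti(img, paths[["cine"]])

  lab <- RNifti::asNifti(to_xyzt(truth$labels))
  RNifti::pixdim(lab) <- c(cine$pixel_spacing, cine$pixel_spacing, dz, dt_s)
  RNifti::writeNifti(lab, paths[["labels"]])

  v <- RNifti::asNifti(array(aperm(vel$velocities, c(2, 3, 1)),
                             dim = c(dim(vel$velocities)[2:3], 1,
                                     dim(vel$velocities)[1])))
  RNifti::pixdim(v) <- c(vel$pixel_spacing, vel$pixel_spacing, 1, dt_s)
  RNifti::writeNifti(v, paths[["velocity"]])

  jsonlite::write_json(list(
    subject_id = id,
    group = subject$group %||% NA,
    height_cm = subject$height %||% NA,
    weight_kg = subject$weight %||% NA,
    cavity_volume_per_phase_ml = truth$cavity_volume_per_phase,
    pnt_volume_per_phase_ml = truth$pnt_volume_per_phase,
    wall_volume_ml = truth$wall_volume,
    total_lvm_true_g = truth$total_lvm_true,
    true_sv_ml = truth$true_sv,
    true_pnt_mass_fraction = truth$true_pnt_mass_fraction
  ), paths[["truth"]], auto_unbox = TRUE, digits = 10)
  invisible(paths)
}

#' Write a cohort to disk with a manifest
#'
#' Calls [write_subject_nifti()] per subject and writes a `manifest.csv`
#' summarizing ids, groups, anthropometrics and ground-truth scalars.
#'
#' @param subjects list of `subject_record`s.
#' @param dir output directory.
#' @return invisibly, the manifest tibble.
#' @export
write_cohort <- function(subjects, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in subjects) write_subject_nifti(s, dir)
  manifest <- purrr::map_dfr(subjects, function(s) {
    tibble::tibble(
      subject_id = s$subject_id, group = s$group,
      height_cm = s$height, weight_kg = s$weight,
      true_sv_ml = s$truth$true_sv,
      total_lvm_true_g = s$truth$total_lvm_true,
      true_pnt_mass_fraction = s$truth$true_pnt_mass_fraction
    )
  })
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a simulated subject back from disk
#'
#' Reconstructs the `cine_stack`, `velocity_series` and ground-truth summary
#' written by [write_subject_nifti()].
#'
#' @param dir directory holding the files.
#' @param id file-name stem.
#' @param slice_thickness,slice_gap slice geometry (mm); the NIfTI header
#'   stores only their sum.
#' @return a list with `cine`, `velocity` and `truth`.
#' @export
read_subject_nifti <- function(dir, id, slice_thickness = 8, slice_gap = 2) {
  img <- RNifti::readNifti(file.path(dir, paste0(id, "_cine.nii.gz")))
  pd <- RNifti::pixdim(img)
  cine <- structure(list(
    intensities = aperm(as.array(img), c(4, 3, 1, 2)),
    pixel_spacing = pd[1],
    slice_thickness = slice_thickness,
    slice_gap = slice_gap,
    phase_duration = pd[4] * 1000
  ), class = "cine_stack")
  vfile <- file.path(dir, paste0(id, "_velocity.nii.gz"))
  velocity <- NULL
  if (file.exists(vfile)) {
    v <- RNifti::readNifti(vfile)
    vd <- RNifti::pixdim(v)
    velocity <- structure(list(
      velocities = aperm(as.array(v)[, , 1, ], c(3, 1, 2)),
      pixel_spacing = vd[1],
      phase_duration = vd[4] * 1000,
      vessel_mask_true = NULL
    ), class = "velocity_series")
  }
  tfile <- file.path(dir, paste0(id, "_truth.json"))
  truth <- if (file.exists(tfile)) jsonlite::read_json(tfile, simplifyVector = TRUE) else NULL
  list(cine = cine, velocity = velocity, truth = truth)
}
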