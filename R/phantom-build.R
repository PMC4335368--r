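# Geometry engine for the cine phantom.
#
# Coordinates: the LV long axis is the z axis, base plane at z = 0, apex at
# z = long_axis_length. Slice index 1 is the most basal slice. All lengths mm.
#
# Tissue classes used internally:
#   0 background, 1 LV blood, 2 compact myocardium, 3 papillary/trabecular
#   tissue (P&T), 4 non-LV blood (basal slab above the base; blood signal but
#   labelled background in the ground truth, since it is not LV cavity).

LV_CLASS_BG    <- 0L
LV_CLASS_BLOOD <- 1L
LV_CLASS_WALL  <- 2L
LV_CLASS_PNT   <- 3L
LV_CLASS_NONLV <- 4L

# raised-cosine contraction curve: 0 at phase 1 (end-diastole), 1 at the
# mid-cycle phase (end-systole)
contraction_curve <- function(n_phases) {
  p <- seq_len(n_phases)
  (1 - cos(2 * pi * (p - 1) / n_phases)) / 2
}

# phase-dependent geometry derived from the spec at contraction value g
phase_geometry <- function(spec, g) {
  s <- sqrt(1 - spec$ejection_fraction_true * g)  # in-plane scale of the smooth cavity
  list(
    a = spec$cavity_semiaxes_ed[1] * s,
    b = spec$cavity_semiaxes_ed[2] * s,
    c = spec$long_axis_length,
    w = spec$wall_thickness_ed + (spec$wall_thickness_es - spec$wall_thickness_ed) * g,
    amp = spec$trabecular_amplitude_ed +
      (spec$trabecular_amplitude_es - spec$trabecular_amplitude_ed) * g
  )
}

# papillary cylinder centres for the geometry of one phase
papillary_centres <- function(spec, geom) {
  n <- spec$papillary_count
  if (n == 0L || spec$papillary_radius <= 0 || spec$papillary_length <= 0) {
    return(NULL)
  }
  psi <- (100 + 360 * (seq_len(n) - 1) / n) * pi / 180
  z0 <- 0.30 * geom$c
  z1 <- min(z0 + spec$papillary_length, 0.95 * geom$c)
  zm <- (z0 + z1) / 2
  mb <- sqrt(max(0, 1 - (zm / geom$c)^2))
  rb <- mb / sqrt((cos(psi) / geom$a)^2 + (sin(psi) / geom$b)^2)
  rc <- pmax(rb - spec$papillary_radius - 1.5, 0.8 * spec$papillary_radius)
  list(x = rc * cos(psi), y = rc * sin(psi), z0 = z0, z1 = z1,
       r2 = spec$papillary_radius^2, cap = 4)
}

# classify a set of points (x, y vectors, z scalar) for one phase geometry
classify_points <- function(spec, geom, pap, x, y, z) {
  cls <- rep.int(LV_CLASS_BG, length(x))
  if (z < 0) {
    if (z >= -spec$basal_slab_length && spec$basal_slab_length > 0) {
      slab_r <- 0.6 * min(spec$cavity_semiaxes_ed)
      cls[(x * x + y * y) <= slab_r^2] <- LV_CLASS_NONLV
    }
    return(cls)
  }
  aw <- geom$a + geom$w; bw <- geom$b + geom$w; cw <- geom$c + geom$w
  m_epi <- (x / aw)^2 + (y / bw)^2 + (z / cw)^2
  inside_epi <- m_epi <= 1
  if (!any(inside_epi)) return(cls)
  m_endo <- (x / geom$a)^2 + (y / geom$b)^2 + (z / geom$c)^2
  inside_endo <- m_endo <= 1
  cls[inside_epi & !inside_endo] <- LV_CLASS_WALL
  idx <- which(inside_endo)
  if (length(idx) == 0L) return(cls)
  xi <- x[idx]; yi <- y[idx]
  cls[idx] <- LV_CLASS_BLOOD
  pnt <- rep.int(FALSE, length(idx))
  # trabecular ridges: sinusoidal radial perturbation of the endocardial radius
  if (geom$amp > 0) {
    theta <- atan2(yi, xi)
    mb <- sqrt(max(0, 1 - (z / geom$c)^2))
    rb <- mb / sqrt((cos(theta) / geom$a)^2 + (sin(theta) / geom$b)^2)
    # power-sharpened profiles give the ridges steep, finger-like flanks;
    # the depth floor makes trabeculae discrete structures - no tissue
    # shallower than trabecular_min_depth, so ridges end in a step rather
    # than an infinitesimal (sub-resolution) wing
    sh <- spec$trabecular_sharpness
    taper <- sin(pi * min(max(z / geom$c, 0), 1))^sh
    ridge <- ((1 + cos(spec$trabecular_angular_frequency * theta +
                         spec$trabecular_phase)) / 2)^sh
    depth <- geom$amp * taper * ridge
    depth[depth < spec$trabecular_min_depth] <- 0
    pnt <- pnt | (sqrt(xi * xi + yi * yi) >= rb - depth)
  }
  if (!is.null(pap) && z >= pap$z0 && z <= pap$z1) {
    # elliptical end caps: the papillary radius tapers over the last few mm
    # instead of ending in a flat knife-edge face
    cap <- min(pap$cap, (pap$z1 - pap$z0) / 2)
    din <- pmin(z - pap$z0, pap$z1 - z)
    shrink <- if (din >= cap) 1 else sqrt(max(0, 1 - ((cap - din) / cap)^2))
    r2_eff <- pap$r2 * shrink^2
    if (r2_eff > 0) {
      for (i in seq_along(pap$x)) {
        pnt <- pnt | ((xi - pap$x[i])^2 + (yi - pap$y[i])^2 <= r2_eff)
      }
    }
  }
  cls[idx[pnt]] <- LV_CLASS_PNT
  cls
}

# block-mean a fine (n*s x n*s) matrix down to (n x n) via sparse-free matmul
block_mean_operator <- function(n, s) {
  if (s == 1L) return(NULL)
  P <- matrix(0, n * s, n)
  P[cbind(seq_len(n * s), rep(seq_len(n), each = s))] <- 1 / s
  P
}

block_mean <- function(fine, P) {
  if (is.null(P)) return(fine)
  crossprod(P, fine %*% P)
}

#' Build a synthetic short-axis cine phantom
#'
#' Renders a [phantom_spec()] into a cine intensity stack (partial-volume
#' voxelization by sub-voxel supersampling, then additive Gaussian noise), a
#' matched through-plane aortic velocity series whose systolic forward-flow
#' integral equals the true cavity stroke volume, and exact ground truth
#' (per-phase label masks and volumes) computed from the noiseless geometry.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed controlling the noise realizations; the output is
#'   bit-identical for identical `spec` and `seed`.
#' @param fov optional in-plane field of view (mm). By default the field of
#'   view is sized to enclose the ventricle; a user-supplied value that is too
#'   small raises an error of class `lvpnt_geometry_error`.
#' @return a list of class `lv_phantom` with elements `cine` (`cine_stack`),
#'   `velocity` (`velocity_series`) and `truth` (`lv_ground_truth`).
#' @export
#' @examples
#' spec <- phantom_spec(n_phases = 6, noise_sd = 0, supersampling_factor = 1)
#' ph <- build_phantom(spec, seed = 1)
#' dim(ph$cine$intensities)
build_phantom <- function(spec, seed = 1L, fov = NULL) {
  validate_phantom_spec(spec)
  w_max <- max(spec$wall_thickness_ed, spec$wall_thickness_es)
  need_half <- max(spec$cavity_semiaxes_ed) + w_max + 2
  if (is.null(fov)) {
    half_fov <- need_half + 6
  } else {
    assert_scalar_num(fov, "fov", positive = TRUE)
    half_fov <- fov / 2
    if (half_fov < need_half) {
      stop_lvpnt(sprintf(
        "field of view %.0f mm is smaller than the ventricle (needs >= %.0f mm)",
        fov, 2 * need_half), "lvpnt_geometry_error")
    }
  }
  px <- spec$pixel_spacing
  n_px <- 2L * as.integer(ceiling(half_fov / px / 2) * 2)  # even, generous
  coords <- (seq_len(n_px) - (n_px + 1) / 2) * px

  dz_slice <- spec$slice_thickness + spec$slice_gap
  n_pre <- if (spec$basal_slab_length > 0) as.integer(ceiling(spec$basal_slab_length / dz_slice)) else 0L
  n_main <- as.integer(ceiling((spec$long_axis_length + w_max) / dz_slice)) + 1L
  n_sl <- n_pre + n_main
  slice_z <- (-(n_pre) + seq_len(n_sl) - 0.5) * dz_slice

  s <- spec$supersampling_factor
  sub <- (seq_len(s) - (s + 1) / 2) / s
  off_xy <- sub * px
  off_z <- sub * spec$slice_thickness
  fine_coords <- as.vector(t(outer(coords, off_xy, "+")))  # length n_px*s, ordered by pixel
  P <- block_mean_operator(n_px, s)
  nf <- n_px * s
  FX <- matrix(fine_coords, nf, nf)          # x varies along rows
  FY <- t(FX)
  class_int <- c(spec$background_intensity, spec$blood_intensity,
                 spec$myocardium_intensity, spec$myocardium_intensity,
                 spec$blood_intensity)

  P_ph <- spec$n_phases
  g_curve <- contraction_curve(P_ph)
  intens <- array(0, dim = c(P_ph, n_sl, n_px, n_px))
  labels <- array(LV_CLASS_BG, dim = c(P_ph, n_sl, n_px, n_px))
  cavity_ml <- numeric(P_ph)
  pnt_ml <- numeric(P_ph)
  wall_ml <- numeric(P_ph)
  vox_ml <- px * px * dz_slice / 1000  # effective voxel volume incl. gap

  for (p in seq_len(P_ph)) {
    geom <- phase_geometry(spec, g_curve[p])
    pap <- papillary_centres(spec, geom)
    for (k in seq_len(n_sl)) {
      acc_int <- 0; acc_bl <- 0; acc_wl <- 0; acc_pn <- 0
      for (iz in seq_len(s)) {
        z <- slice_z[k] + off_z[iz]
        cls <- classify_points(spec, geom, pap, as.vector(FX), as.vector(FY), z)
        dim(cls) <- c(nf, nf)
        acc_int <- acc_int + block_mean(matrix(class_int[cls + 1L], nf, nf), P)
        acc_bl <- acc_bl + block_mean((cls == LV_CLASS_BLOOD) + 0, P)
        acc_wl <- acc_wl + block_mean((cls == LV_CLASS_WALL) + 0, P)
        acc_pn <- acc_pn + block_mean((cls == LV_CLASS_PNT) + 0, P)
      }
      f_bl <- acc_bl / s; f_wl <- acc_wl / s; f_pn <- acc_pn / s
      intens[p, k, , ] <- acc_int / s
      f_bg <- 1 - f_bl - f_wl - f_pn
      lab <- max.col(cbind(as.vector(f_bg) + 1e-9, as.vector(f_bl),
                           as.vector(f_wl), as.vector(f_pn)),
                     ties.method = "first") - 1L
      labels[p, k, , ] <- lab
      cavity_ml[p] <- cavity_ml[p] + sum(f_bl) * vox_ml
      wall_ml[p] <- wall_ml[p] + sum(f_wl) * vox_ml
      pnt_ml[p] <- pnt_ml[p] + sum(f_pn) * vox_ml
    }
  }

  phase_duration <- spec$rr_interval / P_ph
  truth <- structure(list(
    labels = labels,
    label_codes = c(background = 0L, blood = 1L, compact_myocardium = 2L, pnt = 3L),
    cavity_volume_per_phase = cavity_ml,
    pnt_volume_per_phase = pnt_ml,
    wall_volume = wall_ml[1L],
    myocardial_density = 1.05,
    total_lvm_true = (wall_ml[1L] + pnt_ml[1L]) * 1.05,
    true_sv = max(cavity_ml) - min(cavity_ml),
    true_pnt_mass_fraction = pnt_ml[1L] / (wall_ml[1L] + pnt_ml[1L]),
    ed_phase = which.max(cavity_ml),
    es_phase = which.min(cavity_ml),
    slice_z = slice_z
  ), class = "lv_ground_truth")

  velocity <- build_velocity_series(spec, cavity_ml, phase_duration)

  # additive Gaussian noise, clipped at zero (magnitude images are non-negative)
  withr::with_seed(as.integer(seed), {
    if (spec$noise_sd > 0) {
      intens <- intens + array(rnorm(length(intens), 0, spec$noise_sd), dim = dim(intens))
      intens[intens < 0] <- 0
    }
    v_noise_sd <- 0.2 * spec$noise_sd  # cm/s per a.u. of image noise
    if (v_noise_sd > 0) {
      velocity$velocities <- velocity$velocities +
        array(rnorm(length(velocity$velocities), 0, v_noise_sd),
              dim = dim(velocity$velocities))
    }
  })

  cine <- structure(list(
    intensities = intens,
    pixel_spacing = px,
    slice_thickness = spec$slice_thickness,
    slice_gap = spec$slice_gap,
    phase_duration = phase_duration,
    slice_z = slice_z
  ), class = "cine_stack")

  structure(list(cine = cine, velocity = velocity, truth = truth, spec = spec,
                 seed = as.integer(seed)),
            class = "lv_phantom")
}

# Through-plane aortic velocity maps (cm/s). Blunt plug profile with a thin
# power-law boundary layer; per-phase amplitude scaled so the discrete forward
# integral over the true vessel mask reproduces the cavity volume lost between
# consecutive phases exactly (before noise).
build_velocity_series <- function(spec, cavity_ml, phase_duration) {
  px <- spec$pixel_spacing
  R <- spec$vessel_radius
  n_v <- 2L * as.integer(ceiling((R + 8) / px))
  coords <- (seq_len(n_v) - (n_v + 1) / 2) * px
  r <- sqrt(outer(coords^2, coords^2, "+"))
  mask <- as_mask(r <= R)
  profile <- pmax(0, 1 - (r / R)^16) * mask
  P_ph <- spec$n_phases
  nxt <- c(seq_len(P_ph)[-1L], 1L)
  q_ml <- pmax(0, cavity_ml - cavity_ml[nxt])     # outflow volume phase p -> p+1
  px_area_cm2 <- (px / 10)^2
  dt_s <- phase_duration / 1000
  denom <- sum(profile) * px_area_cm2 * dt_s      # ml per unit peak velocity (cm/s)
  vel <- array(0, dim = c(P_ph, n_v, n_v))
  for (p in seq_len(P_ph)) {
    if (q_ml[p] > 0) vel[p, , ] <- (q_ml[p] / denom) * profile
  }
  structure(list(
    velocities = vel,
    pixel_spacing = px,
    phase_duration = phase_duration,
    vessel_mask_true = mask,
    vessel_radius = R
  ), class = "velocity_series")
}

#' @export
print.lv_phantom <- function(x, ...) {
  d <- dim(x$cine$intensities)
  cat(sprintf("<lv_phantom> %d phases x %d slices x %dx%d px\n", d[1], d[2], d[3], d[4]))
  cat(sprintf("  truth: EDV %.1f ml, ESV %.1f ml, SV %.1f ml, LVM %.1f g, P&T fraction %.1f%%\n",
              max(x$truth$cavity_volume_per_phase), min(x$truth$cavity_volume_per_phase),
              x$truth$true_sv, x$truth$total_lvm_true,
              100 * x$truth$true_pnt_mass_fraction))
  invisible(x)
}
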