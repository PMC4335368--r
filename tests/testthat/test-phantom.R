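test_that("phantom specification invariants are enforced", {
  expect_s3_class(phantom_spec(), "phantom_spec")
  expect_error(phantom_spec(ejection_fraction_true = 1), class = "lvpnt_validation_error")
  expect_error(phantom_spec(ejection_fraction_true = 0), class = "lvpnt_validation_error")
  expect_error(phantom_spec(trabecular_amplitude_ed = 2, trabecular_amplitude_es = 3),
               class = "lvpnt_validation_error")
  expect_error(phantom_spec(blood_intensity = 150, myocardium_intensity = 200),
               class = "lvpnt_validation_error")
  expect_error(phantom_spec(n_phases = 1), class = "lvpnt_validation_error")
  expect_error(phantom_spec(long_axis_length = -5), class = "lvpnt_validation_error")
})

test_that("a field of view smaller than the ventricle is rejected", {
  spec <- fix_analytic_spec(supersampling = 1L, n_phases = 2L)
  expect_error(build_phantom(spec, seed = 1, fov = 30), class = "lvpnt_geometry_error")
  expect_s3_class(build_phantom(spec, seed = 1, fov = 120), "lv_phantom")
})

test_that("voxelized cavity volume matches the analytic half-ellipsoid", {
  ph <- build_phantom(fix_analytic_spec(), seed = 1)
  analytic <- (2 / 3) * pi * 20 * 20 * 80 / 1000  # 67.0 ml
  edv <- max(ph$truth$cavity_volume_per_phase)
  expect_lt(abs(edv / analytic - 1), 0.02)
  # no P&T structures anywhere in the cycle
  expect_true(all(ph$truth$pnt_volume_per_phase == 0))
  # the smooth-cavity ejection fraction is realized
  ef <- 1 - min(ph$truth$cavity_volume_per_phase) / edv
  expect_lt(abs(ef - ph$spec$ejection_fraction_true), 0.01)
})

test_that("voxel counting converges to the analytic volume with supersampling", {
  analytic <- (2 / 3) * pi * 20 * 20 * 80 / 1000
  err <- vapply(c(1L, 4L), function(s) {
    ph <- build_phantom(fix_analytic_spec(supersampling = s, n_phases = 2L), seed = 1)
    abs(max(ph$truth$cavity_volume_per_phase) / analytic - 1)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("the phantom is bit-identical under a fixed seed", {
  spec <- draw_phantom_spec(cohort_preset("fabry"), seed = 3,
                            overrides = list(n_phases = 3L))
  a <- build_phantom(spec, seed = 5)
  b <- build_phantom(spec, seed = 5)
  expect_identical(a$cine$intensities, b$cine$intensities)
  expect_identical(a$velocity$velocities, b$velocity$velocities)
  c <- build_phantom(spec, seed = 6)
  expect_false(identical(a$cine$intensities, c$cine$intensities))
})

test_that("ground truth satisfies its structural invariants", {
  ph <- fix_fabry()
  tr <- ph$truth
  expect_equal(tr$true_sv,
               max(tr$cavity_volume_per_phase) - min(tr$cavity_volume_per_phase))
  expect_gte(tr$true_pnt_mass_fraction, 0)
  expect_lt(tr$true_pnt_mass_fraction, 1)
  expect_true(all(ph$cine$intensities >= 0))
  expect_true(all(is.finite(ph$cine$intensities)))
  # compaction: apparent P&T volume is non-increasing from ED to ES
  ed <- tr$ed_phase; es <- tr$es_phase
  pnt <- tr$pnt_volume_per_phase[ed:es]
  expect_true(all(diff(pnt) <= 1e-9))
})

test_that("the noiseless velocity series integrates to the true stroke volume", {
  ph <- fix_noiseless()
  v <- ph$velocity
  px_area <- (v$pixel_spacing / 10)^2
  per_phase <- vapply(seq_len(dim(v$velocities)[1]), function(p) {
    sum(v$velocities[p, , ][v$vessel_mask_true > 0]) * px_area
  }, numeric(1))
  sv <- sum(pmax(per_phase, 0)) * v$phase_duration / 1000
  expect_lt(abs(sv / ph$truth$true_sv - 1), 0.01)
})

test_that("cohort presets are calibrated and ordered", {
  expect_error(cohort_preset("xyz"), class = "lvpnt_validation_error")
  ctrl <- cohort_preset("control")
  fab <- cohort_preset("fabry")
  expect_gt(fab$wall_thickness_ed, ctrl$wall_thickness_ed)
  expect_equal(fab$pnt_fraction_target, 0.20)
  expect_equal(ctrl$pnt_fraction_target, 0.13)
})

test_that("preset draws hit the documented ground-truth fraction targets", {
  # cheap builds: two phases suffice for the end-diastolic truth fraction
  frac <- function(name, n) {
    mean(vapply(seq_len(n), function(i) {
      spec <- draw_phantom_spec(cohort_preset(name), seed = 100 + i,
                                overrides = list(n_phases = 2L))
      build_phantom(spec, seed = i)$truth$true_pnt_mass_fraction
    }, numeric(1)))
  }
  expect_lt(abs(frac("control", 30) - 0.13), 0.02)
  expect_lt(abs(frac("fabry", 30) - 0.20), 0.02)
})

test_that("generate_cohort is deterministic and validates its input", {
  expect_error(generate_cohort("fabry", -1), class = "lvpnt_validation_error")
  expect_identical(generate_cohort("fabry", 0), list())
  a <- generate_cohort("fabry", 2, seed = 9, overrides = list(n_phases = 2L))
  b <- generate_cohort("fabry", 2, seed = 9, overrides = list(n_phases = 2L))
  expect_identical(a[[1]]$cine$intensities, b[[1]]$cine$intensities)
  expect_identical(a[[2]]$truth$true_sv, b[[2]]$truth$true_sv)
  for (s in a) {
    expect_gt(s$height, 0)
    expect_gt(s$weight, 0)
    expect_gt(s$truth$true_pnt_mass_fraction, 0)
    expect_s3_class(s$spec, "phantom_spec")
  }
})
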