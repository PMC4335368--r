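make_velocity <- function(vel_array, px = 1, dt_ms = 100, mask = NULL) {
  structure(list(velocities = vel_array, pixel_spacing = px,
                 phase_duration = dt_ms, vessel_mask_true = mask),
            class = "velocity_series")
}

test_that("flow integration is velocity times area times time", {
  # 50 cm/s over 5 cm^2 for 0.4 s of forward flow -> 100 ml
  n <- 10
  roi <- matrix(0L, n, n)
  roi[1:50] <- 1L                         # 50 px of 10 mm^2 each = 5 cm^2
  vel <- array(0, dim = c(5, n, n))
  for (p in 1:4) vel[p, , ][roi > 0] <- 50  # 4 phases x 0.1 s
  v <- make_velocity(vel, px = sqrt(10), dt_ms = 100)
  fm <- integrate_flow(v, roi)
  expect_equal(fm$aortic_sv, 100, tolerance = 1e-10)
  expect_equal(fm$roi_area, 5, tolerance = 1e-10)
  expect_length(fm$per_phase_flow, 5)
  expect_equal(fm$per_phase_flow[5], 0)
})

test_that("only forward flow enters the stroke volume", {
  vel <- array(0, dim = c(2, 4, 4))
  vel[1, , ] <- 10
  vel[2, , ] <- -10                        # reverse phase is not subtracted
  v <- make_velocity(vel, px = 10, dt_ms = 1000)
  fm <- integrate_flow(v, matrix(1L, 4, 4))
  expect_equal(fm$aortic_sv, 10 * 16 * 1)  # cm/s * cm^2 * s
})

test_that("stroke volume is linear in velocity", {
  ph <- fix_fabry()
  v <- ph$velocity
  roi <- detect_vessel_roi(v)
  sv1 <- integrate_flow(v, roi)$aortic_sv
  v2 <- v; v2$velocities <- 3 * v$velocities
  expect_equal(integrate_flow(v2, roi)$aortic_sv, 3 * sv1, tolerance = 1e-10)
})

test_that("flow errors on degenerate input", {
  v <- make_velocity(array(0, dim = c(2, 4, 4)))
  expect_error(detect_vessel_roi(v), class = "lvpnt_flow_error")
  vv <- make_velocity(array(1, dim = c(2, 4, 4)))
  expect_error(integrate_flow(vv, matrix(0L, 4, 4)), class = "lvpnt_flow_error")
  expect_error(integrate_flow(vv, matrix(1L, 5, 5)), class = "lvpnt_validation_error")
  expect_error(detect_vessel_roi(list()), class = "lvpnt_validation_error")
})

test_that("the detected vessel ROI matches the true lumen", {
  ph <- fix_noiseless()
  roi <- detect_vessel_roi(ph$velocity)
  truth <- ph$velocity$vessel_mask_true
  d <- 2 * sum(roi > 0 & truth > 0) / (sum(roi) + sum(truth))
  expect_gte(d, 0.9)
  area <- sum(roi) * (ph$velocity$pixel_spacing / 10)^2
  expect_lt(abs(area / (pi * (ph$spec$vessel_radius / 10)^2) - 1), 0.10)
  expect_equal(attr(roi, "source"), "detected")
  expect_equal(attr(detect_vessel_roi(ph$velocity, use_true_mask = TRUE), "source"),
               "true")
})

test_that("aortic stroke volume conserves the cavity stroke volume", {
  ph <- fix_noiseless()
  seg <- fix_noiseless_seg()
  roi <- detect_vessel_roi(ph$velocity)
  sv <- integrate_flow(ph$velocity, roi)$aortic_sv
  expect_lt(abs(sv / ph$truth$true_sv - 1), 0.01)
  minc <- ventricular_measures(seg, "minc")
  expect_lte(abs(minc$lvsv - sv) / ph$truth$true_sv, 0.03)
})

test_that("velocity noise leaves the cohort-mean stroke volume unbiased", {
  subs <- fix_cohort()
  fab <- subs[vapply(subs, `[[`, "", "group") == "fabry"]
  d <- vapply(fab, function(s) {
    roi <- detect_vessel_roi(s$velocity)
    integrate_flow(s$velocity, roi)$aortic_sv - s$truth$true_sv
  }, numeric(1))
  sv <- vapply(fab, function(s) {
    integrate_flow(s$velocity, detect_vessel_roi(s$velocity))$aortic_sv
  }, numeric(1))
  se <- stats::sd(sv) / sqrt(length(sv))
  expect_lt(abs(mean(d)), se)
})
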