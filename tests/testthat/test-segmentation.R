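test_that("end-diastole and end-systole are located on the volume curve", {
  expect_equal(find_ed_es_phases(c(100, 80, 60, 80)), list(ed = 1L, es = 3L))
  expect_equal(find_ed_es_phases(c(50, 50, 50)), list(ed = 1L, es = 1L))
  curve <- cos(2 * pi * (0:19) / 20)          # raised cosine, minimum at phase 11
  expect_equal(find_ed_es_phases(curve), list(ed = 1L, es = 11L))
  expect_error(find_ed_es_phases(c(1)), class = "lvpnt_validation_error")
  expect_error(find_ed_es_phases(c(1, NA, 3)), class = "lvpnt_validation_error")
})

test_that("free-wall reference statistics are the sample mean and SD", {
  img <- matrix(0, 20, 20)
  wall <- matrix(0L, 20, 20)
  # three ROI pixels on the +row side of the mask centroid; a fourth far
  # pixel shifts the centroid so all three fall inside the lateral sector
  wall[c(14, 15, 16), 10] <- 1L
  wall[4, 10] <- 1L
  img[14, 10] <- 390; img[15, 10] <- 400; img[16, 10] <- 410
  img[4, 10] <- 9999
  st <- freewall_reference_stats(img, wall)
  expect_equal(st$mean, 400)
  expect_equal(st$sd, 10)

  uni <- matrix(400, 20, 20)
  st2 <- freewall_reference_stats(uni, wall)
  expect_equal(st2$mean, 400)
  expect_equal(st2$sd, 0)

  expect_error(freewall_reference_stats(img, matrix(0L, 20, 20)),
               class = "lvpnt_segmentation_error")
  expect_error(freewall_reference_stats(img, matrix(0L, 5, 5)),
               class = "lvpnt_validation_error")
})

test_that("the intensity band rule classifies P&T pixels", {
  img <- matrix(c(430, 1000, 451, 450), 2, 2)
  cav <- matrix(1L, 2, 2)
  pnt <- classify_pnt(img, cav, mean = 400, sd = 50)
  expect_equal(as.vector(pnt), c(1L, 0L, 0L, 1L))  # inclusive band, 451 is out
  # sd = 0 degenerates to exact equality
  pnt0 <- classify_pnt(matrix(c(400, 400.1), 1, 2), matrix(1L, 1, 2), 400, 0)
  expect_equal(as.vector(pnt0), c(1L, 0L))
  expect_error(classify_pnt(img, matrix(1L, 3, 3), 400, 50),
               class = "lvpnt_validation_error")
})

test_that("the band grows monotonically with the SD multiplier", {
  withr::with_seed(4, {
    img <- matrix(rnorm(400, 300, 80), 20, 20)
    cav <- matrix(1L, 20, 20)
    sizes <- vapply(c(0.5, 1, 1.5, 2), function(k) {
      sum(classify_pnt(img, cav, 300, 50,
                       segmentation_config(intensity_band_sd = k)))
    }, numeric(1))
    expect_true(all(diff(sizes) >= 0))
  })
})

test_that("trabeculae below the minimum width are removed, at it kept", {
  px <- 0.5  # mm per pixel: the 1.5 mm rule spans 3 pixels
  m <- matrix(0L, 40, 40)
  m[5:6, 5:30] <- 1L     # 1.0 mm wide ridge -> below threshold, removed
  m[15:17, 5:30] <- 1L   # exactly 1.5 mm wide -> kept
  m[25:34, 5:14] <- 1L   # 5 mm block (papillary cross-section) -> kept
  out <- filter_thin_trabeculae(m, px)
  expect_equal(sum(out[5:6, ]), 0)
  expect_equal(sum(out[15:17, 5:30]), sum(m[15:17, 5:30]))
  expect_equal(sum(out[25:34, 5:14]), 100)
  # empty in, empty out
  expect_equal(sum(filter_thin_trabeculae(matrix(0L, 10, 10), px)), 0)
})

test_that("the width filter is idempotent and anti-extensive", {
  withr::with_seed(11, {
    for (i in 1:5) {
      m <- matrix(as.integer(runif(900) > 0.7), 30, 30)
      f1 <- filter_thin_trabeculae(m, 0.5)
      f2 <- filter_thin_trabeculae(f1, 0.5)
      expect_true(all(f1 <= m))        # anti-extensive
      expect_identical(f1, f2)         # idempotent
    }
  })
})

test_that("the smooth contour returns P&T to the blood pool", {
  d <- 40
  ctr <- 20.5
  rr <- sqrt(outer((1:d - ctr)^2, (1:d - ctr)^2, "+"))
  wall <- as.integer(rr <= 15 & rr > 10); dim(wall) <- c(d, d)
  pnt <- as.integer(rr <= 10 & rr > 8 &
                      outer(1:d - ctr, rep(1, d)) > 0 &
                      abs(outer(rep(1, d), 1:d - ctr)) < 3)
  dim(pnt) <- c(d, d)
  blood <- sum(rr <= 10) - sum(pnt)
  mex <- smooth_endocardial_contour(wall, pnt, pixel_spacing = 1)
  expect_gte(sum(mex), blood)                 # superset of the blood-only cavity
  expect_true(all(mex[pnt > 0] == 1))         # P&T inside the smooth cavity
  # without a cavity there is nothing to contour
  solid <- matrix(1L, 10, 10)
  expect_error(smooth_endocardial_contour(solid, matrix(0L, 10, 10)),
               class = "lvpnt_segmentation_error")
  expect_error(smooth_endocardial_contour(wall, matrix(0L, 5, 5)),
               class = "lvpnt_validation_error")
})

test_that("basal and apical slices follow the enclosure and blood-pool rules", {
  d <- 30; ctr <- 15.5
  rr <- sqrt(outer((1:d - ctr)^2, (1:d - ctr)^2, "+"))
  cavity <- as_matrix <- function(x) { dim(x) <- c(d, d); x }
  cav <- as_matrix(as.integer(rr <= 8))
  ring <- as_matrix(as.integer(rr <= 13 & rr > 8))
  none <- matrix(0L, d, d)
  # slice 1: cavity with no myocardium (atrium-like) -> not basal
  sel <- select_slices(list(cav, cav, cav, none), list(none, ring, ring, none))
  expect_equal(sel$basal, 2L)
  expect_equal(sel$apical, 3L)
  # fully enclosed stack -> full range
  sel2 <- select_slices(list(cav, cav), list(ring, ring))
  expect_equal(sel2$basal, 1L)
  expect_equal(sel2$apical, 2L)
  # nothing qualifies
  expect_error(select_slices(list(cav), list(none)),
               class = "lvpnt_segmentation_error")
})

test_that("subject segmentation recovers the true phases and is consistent", {
  ph <- fix_fabry()
  seg <- fix_fabry_seg()
  expect_equal(seg$ed_phase, ph$truth$ed_phase)
  expect_equal(seg$es_phase, ph$truth$es_phase)
  expect_lte(seg$basal_slice, seg$apical_slice)
  # the pre-basal blood-only slab is excluded
  expect_gt(seg$basal_slice, 1L)
  # per-slice: the smooth-contour cavity contains the blood-only cavity and
  # the P&T mask lies inside it
  for (phs in c("ed", "es")) {
    for (k in seg$basal_slice:seg$apical_slice) {
      mex <- seg[[phs]]$mex_cavity[k, , ]
      minc <- seg[[phs]]$minc_cavity[k, , ]
      pnt <- seg[[phs]]$pnt[k, , ]
      expect_gte(sum(mex), sum(minc))
      expect_equal(sum(pnt > 0 & mex == 0), 0)
    }
  }
  # epicardium encloses the end-diastolic cavity
  k <- floor((seg$basal_slice + seg$apical_slice) / 2)
  expect_true(all(seg$ed$epi[k, , ][seg$ed$minc_cavity[k, , ] > 0] == 1))
})

test_that("degenerate contrast aborts with a diagnostic", {
  withr::with_seed(2, {
    arr <- array(abs(rnorm(2 * 3 * 40 * 40, 100, 15)), dim = c(2, 3, 40, 40))
  })
  cine <- structure(list(intensities = arr, pixel_spacing = 1.4,
                         slice_thickness = 8, slice_gap = 2,
                         phase_duration = 50), class = "cine_stack")
  expect_error(segment_subject(cine), class = "lvpnt_contrast_error")
})

test_that("without P&T structures the two conventions coincide", {
  ph <- build_phantom(fix_analytic_spec(supersampling = 2L, n_phases = 6L), seed = 2)
  seg <- segment_subject(ph$cine)
  m_inc <- ventricular_measures(seg, "minc")
  m_ex <- ventricular_measures(seg, "mex")
  expect_lt(abs(m_ex$lvedv / m_inc$lvedv - 1), 0.02)
  expect_lt(abs(m_ex$lvesv / m_inc$lvesv - 1), 0.02)
  expect_lt(abs(m_ex$lvm / m_inc$lvm - 1), 0.02)
})

test_that("noiseless segmentation matches ground-truth labels per class", {
  ph <- fix_noiseless()
  seg <- fix_noiseless_seg()
  rng <- seg$basal_slice:seg$apical_slice
  lab <- ph$truth$labels[seg$ed_phase, , , ]
  dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
  expect_gte(dice(seg$ed$minc_cavity[rng, , ] > 0, lab[rng, , ] == 1), 0.95)
  expect_gte(dice(seg$ed$wall[rng, , ] > 0, lab[rng, , ] == 2), 0.95)
  expect_gte(dice(seg$ed$pnt[rng, , ] > 0, lab[rng, , ] == 3), 0.95)
})
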