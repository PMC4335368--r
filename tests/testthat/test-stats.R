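test_that("the paired t-test matches its closed form and edge cases", {
  x <- c(1, 2, 3, 4); y <- c(2, 2, 4, 5)
  res <- paired_t(x, y)
  # d = (-1, 0, -1, -1): mean -0.75, sd 0.5, t = -0.75 / (0.5 / 2) = -3
  expect_equal(res$statistic, -3, tolerance = 1e-10)
  expect_equal(res$df, 3)
  expect_equal(res$p_value, 2 * stats::pt(-3, 3), tolerance = 1e-10)
  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(paired_t(c(1, 2, 3), c(2, 3, 4)), class = "lvpnt_degenerate_error")
  expect_error(paired_t(1, 2), class = "lvpnt_validation_error")
})

test_that("the independent t-test uses the Welch form by default", {
  x <- c(1, 2, 3); y <- c(2, 4, 6, 8)
  res <- independent_t(x, y)
  # Welch statistic and df computed from first principles
  se2 <- stats::var(x) / 3 + stats::var(y) / 4
  t_exp <- (mean(x) - mean(y)) / sqrt(se2)
  df_exp <- se2^2 / ((stats::var(x) / 3)^2 / 2 + (stats::var(y) / 4)^2 / 3)
  expect_equal(res$statistic, t_exp, tolerance = 1e-10)
  expect_equal(res$df, df_exp, tolerance = 1e-10)
  expect_equal(res$p_value, 2 * stats::pt(-abs(t_exp), df_exp), tolerance = 1e-10)
  same <- independent_t(c(5, 5), c(5, 5))
  expect_equal(same$p_value, 1)
  expect_error(independent_t(c(0, 0), c(1, 1)), class = "lvpnt_degenerate_error")
  expect_error(independent_t(1, c(1, 2)), class = "lvpnt_validation_error")
  # Student option reduces to the pooled form
  stud <- independent_t(x, y, var_equal = TRUE)
  expect_equal(stud$df, 5)
})

test_that("t-test p-values agree with permutation oracles", {
  withr::with_seed(21, {
    x <- rnorm(30, 0.3); y <- rnorm(30)
    # paired: sign-flip permutation of the differences
    d <- x - y
    t_obs <- abs(paired_t(x, y)$statistic)
    flips <- replicate(2000, {
      s <- sample(c(-1, 1), length(d), replace = TRUE)
      ds <- d * s
      abs(mean(ds) / (stats::sd(ds) / sqrt(length(ds))))
    })
    p_perm <- mean(flips >= t_obs)
    expect_lt(abs(paired_t(x, y)$p_value - p_perm), 0.05)
    # independent: label permutation
    t_obs2 <- abs(independent_t(x, y)$statistic)
    pool <- c(x, y)
    perms <- replicate(2000, {
      idx <- sample(length(pool), length(x))
      abs(independent_t(pool[idx], pool[-idx])$statistic)
    })
    p_perm2 <- mean(perms >= t_obs2)
    expect_lt(abs(independent_t(x, y)$p_value - p_perm2), 0.05)
  })
})

test_that("Bland-Altman fields follow their closed form", {
  ba <- bland_altman(c(2, 4, 6), c(1, 2, 3))
  # d = (1, 2, 3): mean 2, sd 1
  expect_equal(ba$mean_difference, 2)
  expect_equal(ba$sd_difference, 1)
  expect_equal(ba$loa_lower, 2 - 1.96)
  expect_equal(ba$loa_upper, 2 + 1.96)
  expect_equal(ba$coefficient_of_repeatability, 1.96)
  expect_equal(ba$n, 3L)
  zero <- bland_altman(c(1, 2), c(1, 2))
  expect_equal(zero$mean_difference, 0)
  expect_equal(zero$coefficient_of_repeatability, 0)
  expect_error(bland_altman(1, 1), class = "lvpnt_validation_error")
  # limits contain the mean difference; CR invariant under shifts
  withr::with_seed(3, {
    a <- rnorm(40); b <- rnorm(40)
    ba2 <- bland_altman(a, b)
    expect_lte(ba2$loa_lower, ba2$mean_difference)
    expect_gte(ba2$loa_upper, ba2$mean_difference)
    ba3 <- bland_altman(a + 100, b + 100)
    expect_equal(ba3$coefficient_of_repeatability,
                 ba2$coefficient_of_repeatability, tolerance = 1e-12)
  })
})

test_that("about 95% of normal differences fall within the limits of agreement", {
  withr::with_seed(8, {
    x <- rnorm(1e4, 5, 2); y <- rnorm(1e4, 4, 1)
    ba <- bland_altman(x, y)
    d <- x - y
    frac <- mean(d >= ba$loa_lower & d <= ba$loa_upper)
    expect_gt(frac, 0.94)
    expect_lt(frac, 0.96)
  })
})

test_that("tidy, glance and autoplot work on Bland-Altman results", {
  ba <- bland_altman(c(2, 4, 6), c(1, 2, 3))
  td <- tidy(ba)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3L)
  gl <- glance(ba)
  expect_equal(gl$coefficient_of_repeatability, 1.96)
  p <- ggplot2::autoplot(ba)
  expect_s3_class(p, "ggplot")
})

test_that("the cohort table reproduces the directional method differences", {
  mm <- fix_measures()
  tab <- cohort_table(mm)
  expect_s3_class(tab, "cohort_summary")
  md <- tab$method_comparison
  for (g in unique(mm$group)) {
    expect_lt(md$mean_diff[md$group == g & md$measure == "lvedv"], 0)  # mex larger
    expect_lt(md$mean_diff[md$group == g & md$measure == "lvesv"], 0)
    expect_gt(md$mean_diff[md$group == g & md$measure == "lvm"], 0)    # minc larger
    expect_gt(md$mean_diff[md$group == g & md$measure == "lvef"], 0)
  }
  # P&T reassignment is strongly significant within groups even at small n
  expect_lt(md$p_value[md$group == "fabry" & md$measure == "lvm"], 0.05)
  expect_equal(nrow(tab$group_comparison), 12L)  # 6 measures x 2 methods
})

test_that("degenerate and malformed cohorts are rejected", {
  mm <- fix_measures()
  expect_error(cohort_table(mm[mm$method == "minc", ]),
               class = "lvpnt_validation_error")
  one <- mm[mm$subject_id == mm$subject_id[1], ]
  expect_error(cohort_table(one), class = "lvpnt_validation_error")
  # identical methods: differences are zero, p-values degenerate to NA
  same <- mm
  same[same$method == "mex", c("lvedv", "lvesv", "lvsv", "lvef", "lvm",
                               "lvm_indexed")] <-
    same[same$method == "minc", c("lvedv", "lvesv", "lvsv", "lvef", "lvm",
                                  "lvm_indexed")]
  tab <- cohort_table(same)
  expect_true(all(tab$method_comparison$mean_diff == 0))
  expect_true(all(is.na(tab$method_comparison$p_value) |
                    tab$method_comparison$p_value == 1))
})

test_that("flow concordance separates the two conventions", {
  mm <- fix_measures()
  fab <- mm[mm$group == "fabry", ]
  inc <- flow_concordance(fab, "minc")
  ex <- flow_concordance(fab, "mex")
  expect_lt(abs(inc$mean_diff), 5)
  expect_gt(ex$mean_diff, inc$mean_diff)   # excluding P&T overestimates SV
  expect_equal(inc$n, 4L)
  noflow <- fab[, setdiff(names(fab), "aortic_sv")]
  expect_error(flow_concordance(noflow, "minc"), class = "lvpnt_validation_error")
  expect_error(flow_concordance(fab[0, ], "minc"), class = "lvpnt_validation_error")
})

test_that("zero perturbation yields an all-zero repeatability analysis", {
  subs <- fix_cohort()[1:4]
  rep0 <- observer_repeatability(subs, roi_rotation = 0, redraw_noise = FALSE)
  expect_named(rep0, c("lvedv", "lvesv"))
  for (ba in rep0) {
    expect_equal(ba$mean_difference, 0)
    expect_equal(ba$coefficient_of_repeatability, 0)
  }
  expect_error(observer_repeatability(list()), class = "lvpnt_validation_error")
})

test_that("repeatability worsens with image noise", {
  quiet <- generate_cohort("fabry", 4, seed = 51,
                           overrides = list(n_phases = 8L, noise_sd = 4))
  loud <- generate_cohort("fabry", 4, seed = 51,
                          overrides = list(n_phases = 8L, noise_sd = 24))
  cr <- function(subs) {
    r <- observer_repeatability(subs, perturbation_seed = 9)
    r$lvedv$coefficient_of_repeatability + r$lvesv$coefficient_of_repeatability
  }
  expect_lt(cr(quiet), cr(loud))
})
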