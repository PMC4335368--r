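#' Paired-samples t-test
#'
#' Classical paired t-test on the differences `x - y`, two-sided p-value from
#' the t distribution with n - 1 degrees of freedom. Identical vectors return
#' t = 0 and p = 1; non-zero constant differences are degenerate (no
#' within-pair variance) and raise an error.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return a one-row tibble with `statistic`, `p_value`, `df`, `mean_diff`,
#'   `sd_diff` and `n`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop_lvpnt("paired_t needs two equal-length vectors of length >= 2",
               "lvpnt_validation_error")
  }
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble::tibble(statistic = 0, p_value = 1, df = length(d) - 1,
                            mean_diff = 0, sd_diff = 0, n = length(d)))
    }
    stop_lvpnt("degenerate paired test: constant non-zero differences",
               "lvpnt_degenerate_error")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
                 df = unname(tt$parameter), mean_diff = mean(d),
                 sd_diff = stats::sd(d), n = length(d))
}

#' Independent-samples t-test
#'
#' Welch's unequal-variance form by default; Student's pooled-variance form
#' via `var_equal = TRUE`. Identical groups return t = 0, p = 1; zero
#' variance in both groups with differing means is degenerate.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param var_equal use the pooled-variance (Student) form.
#' @return a one-row tibble with `statistic`, `p_value`, `df`, `mean_x`,
#'   `mean_y`.
#' @export
independent_t <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2L || length(y) < 2L) {
    stop_lvpnt("independent_t needs two vectors of length >= 2",
               "lvpnt_validation_error")
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(tibble::tibble(statistic = 0, p_value = 1,
                            df = length(x) + length(y) - 2,
                            mean_x = mean(x), mean_y = mean(y)))
    }
    stop_lvpnt("degenerate independent test: zero variance in both groups",
               "lvpnt_degenerate_error")
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  tibble::tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
                 df = unname(tt$parameter), mean_x = mean(x), mean_y = mean(y))
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = x - y`: mean difference, SD of differences, 95% limits of
#' agreement (mean +/- `cr_multiplier` * SD) and the coefficient of
#' repeatability (`cr_multiplier` * SD of differences; 1.96 by default, some
#' literature uses 2).
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @param cr_multiplier multiplier on the SD of differences. Default 1.96.
#' @return an object of class `bland_altman` with fields `mean_difference`,
#'   `sd_difference`, `loa_lower`, `loa_upper`,
#'   `coefficient_of_repeatability`, `n`, plus the per-pair means and
#'   differences for plotting. Supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @export
#' @examples
#' ba <- bland_altman(c(2, 4, 6), c(1, 2, 3))
#' glance(ba)
bland_altman <- function(x, y, cr_multiplier = 1.96) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop_lvpnt("bland_altman needs two equal-length vectors of length >= 2",
               "lvpnt_validation_error")
  }
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(
    mean_difference = m,
    sd_difference = s,
    loa_lower = m - cr_multiplier * s,
    loa_upper = m + cr_multiplier * s,
    coefficient_of_repeatability = cr_multiplier * s,
    cr_multiplier = cr_multiplier,
    n = length(d),
    means = (x + y) / 2,
    differences = d
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d, mean diff %.3f, LoA [%.3f, %.3f], CR %.3f\n",
              x$n, x$mean_difference, x$loa_lower, x$loa_upper,
              x$coefficient_of_repeatability))
  invisible(x)
}

#' Tidy a Bland-Altman result
#'
#' @param x a `bland_altman` object.
#' @param ... unused.
#' @return per-pair tibble of means and differences.
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(mean = x$means, difference = x$differences)
}

#' One-row summary of a Bland-Altman result
#'
#' @param x a `bland_altman` object.
#' @param ... unused.
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(mean_difference = x$mean_difference,
                 sd_difference = x$sd_difference,
                 loa_lower = x$loa_lower, loa_upper = x$loa_upper,
                 coefficient_of_repeatability = x$coefficient_of_repeatability,
                 n = x$n)
}

#' Turn a result object into a tidy tibble
#'
#' Generic in the broom style; methods exist for the package's result
#' objects.
#' @param x a result object.
#' @param ... passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model/result summary
#'
#' Generic in the broom style; methods exist for the package's result
#' objects.
#' @param x a result object.
#' @param ... passed to methods.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Cohort summary table
#'
#' Summarizes per-subject measures into a cohort table: per group and method,
#' mean and standard error of the mean (SEM = SD / sqrt(n)) of each measure,
#' with within-group paired p-values comparing the two conventions and
#' between-group p-values per method (Welch by default).
#'
#' @param measures tibble from [measure_cohort()]: one row per subject and
#'   method, with a `group`, `subject_id` and `method` column.
#' @param vars measure columns to summarize.
#' @param var_equal use Student instead of Welch for between-group tests.
#' @return a list of class `cohort_summary`: `$summary` (group x method x
#'   measure means and SEMs), `$method_comparison` (paired p within group) and
#'   `$group_comparison` (between-group p per method).
#' @export
cohort_table <- function(measures,
                         vars = c("lvedv", "lvesv", "lvsv", "lvef", "lvm",
                                  "lvm_indexed"),
                         var_equal = FALSE) {
  needed <- c("subject_id", "group", "method")
  if (!all(needed %in% names(measures))) {
    stop_lvpnt("`measures` must have subject_id, group and method columns",
               "lvpnt_validation_error")
  }
  vars <- intersect(vars, names(measures))
  counts <- dplyr::count(measures, .data$group, .data$subject_id)
  if (any(counts$n != 2L)) {
    stop_lvpnt("every subject needs measures for both methods",
               "lvpnt_validation_error")
  }
  if (any(table(measures$group) < 4L)) {  # < 2 subjects per group
    stop_lvpnt("need at least 2 subjects per group for SEM and t-tests",
               "lvpnt_validation_error")
  }
  long <- tidyr::pivot_longer(
    measures[, c(needed, vars)], dplyr::all_of(vars),
    names_to = "measure", values_to = "value")
  summary <- long |>
    dplyr::group_by(.data$group, .data$method, .data$measure) |>
    dplyr::summarise(mean = mean(.data$value),
                     sem = stats::sd(.data$value) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  wide <- tidyr::pivot_wider(long, names_from = "method", values_from = "value")
  safe_p <- function(f) tryCatch(f()$p_value, lvpnt_degenerate_error = function(e) NA_real_)
  method_cmp <- wide |>
    dplyr::group_by(.data$group, .data$measure) |>
    dplyr::summarise(
      mean_diff = mean(.data$minc - .data$mex),
      p_value = safe_p(function() paired_t(.data$minc, .data$mex)),
      .groups = "drop")
  groups <- unique(measures$group)
  group_cmp <- NULL
  if (length(groups) == 2L) {
    group_cmp <- long |>
      dplyr::group_by(.data$method, .data$measure) |>
      dplyr::summarise(
        p_value = safe_p(function() independent_t(
          .data$value[.data$group == groups[1]],
          .data$value[.data$group == groups[2]], var_equal = var_equal)),
        .groups = "drop")
  }
  structure(list(summary = summary, method_comparison = method_cmp,
                 group_comparison = group_cmp),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n$summary\n")
  print(x$summary, n = Inf)
  cat("\n$method_comparison\n")
  print(x$method_comparison, n = Inf)
  if (!is.null(x$group_comparison)) {
    cat("\n$group_comparison\n")
    print(x$group_comparison, n = Inf)
  }
  invisible(x)
}

#' Concordance of volumetric and flow-derived stroke volume
#'
#' Per subject, the difference between the volumetric stroke volume of the
#' chosen convention and the flow-derived aortic stroke volume; returns the
#' cohort mean difference, its SEM, and the paired-t p-value against zero.
#'
#' @param measures tibble from [measure_cohort()] including an `aortic_sv`
#'   column.
#' @param method `"minc"` or `"mex"`.
#' @return one-row tibble with `method`, `mean_diff` (ml), `sem`, `p_value`,
#'   `n`.
#' @export
flow_concordance <- function(measures, method = c("minc", "mex")) {
  method <- match.arg(method)
  if (!"aortic_sv" %in% names(measures) || all(is.na(measures$aortic_sv))) {
    stop_lvpnt("measures carry no aortic flow column", "lvpnt_validation_error")
  }
  m <- measures[measures$method == method, ]
  if (nrow(m) == 0L) stop_lvpnt("empty cohort", "lvpnt_validation_error")
  d <- m$lvsv - m$aortic_sv
  p <- if (length(d) >= 2L && stats::sd(d) > 0) {
    unname(stats::t.test(d)$p.value)
  } else NA_real_
  tibble::tibble(method = method, mean_diff = mean(d),
                 sem = stats::sd(d) / sqrt(length(d)),
                 p_value = p, n = length(d))
}

#' Simulated observer repeatability
#'
#' Emulates repeated measurement of end-diastolic and end-systolic volumes on
#' half of the cohort: the second "observation" re-runs segmentation on a
#' re-rendering of the same subject with a fresh noise realization and with
#' the free-wall reference sector rotated by `roi_rotation` degrees (nuisance
#' perturbations standing in for a human re-read; this is a stand-in, not a
#' claim of equivalence to human observers).
#'
#' @param subjects list of `subject_record`s carrying their `spec`.
#' @param perturbation_seed integer seed for the repeat noise realizations.
#' @param roi_rotation free-wall sector rotation for the repeat read, degrees.
#' @param redraw_noise draw a fresh noise realization for the repeat read.
#' @param vars measures to analyse.
#' @param seg_config a [segmentation_config()].
#' @return named list of `bland_altman` objects, one per measure, over the
#'   first ceiling(n/2) subjects.
#' @export
observer_repeatability <- function(subjects, perturbation_seed = 1L,
                                   roi_rotation = 15, redraw_noise = TRUE,
                                   vars = c("lvedv", "lvesv"),
                                   seg_config = segmentation_config()) {
  if (length(subjects) < 4L) {
    stop_lvpnt("repeatability needs at least 4 subjects (2 re-read)",
               "lvpnt_validation_error")
  }
  half <- subjects[seq_len(ceiling(length(subjects) / 2))]
  cfg2 <- seg_config
  cfg2$freewall_angle <- seg_config$freewall_angle + roi_rotation
  reads <- lapply(half, function(sub) {
    m1 <- ventricular_measures(segment_subject(sub$cine, seg_config), "minc")
    cine2 <- sub$cine
    if (redraw_noise && !is.null(sub$spec)) {
      ph2 <- build_phantom(sub$spec, seed = derive_seed(perturbation_seed, sub$seed %% 1000L))
      cine2 <- ph2$cine
    }
    m2 <- ventricular_measures(segment_subject(cine2, cfg2), "minc")
    list(m1 = m1, m2 = m2)
  })
  out <- lapply(vars, function(v) {
    bland_altman(vapply(reads, function(r) r$m1[[v]], numeric(1)),
                 vapply(reads, function(r) r$m2[[v]], numeric(1)))
  })
  names(out) <- vars
  out
}
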