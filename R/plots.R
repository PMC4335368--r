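#' Bland-Altman plot
#'
#' Scatter of per-pair means against differences with the mean difference
#' (solid) and the limits of agreement (dashed).
#'
#' @param object a [bland_altman()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = object$mean_difference, linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of paired measurements",
                  y = "Difference",
                  title = sprintf("Bland-Altman (CR = %.2f)",
                                  object$coefficient_of_repeatability)) +
    ggplot2::theme_minimal()
}

#' Cavity volume curve of a segmented subject
#'
#' Blood-pool volume over the cardiac cycle with the detected end-diastolic
#' and end-systolic phases marked.
#'
#' @param seg an `lv_segmentation` from [segment_subject()].
#' @return a ggplot object.
#' @export
plot_volume_curve <- function(seg) {
  df <- tibble::tibble(phase = seq_along(seg$volume_curve),
                       volume = seg$volume_curve)
  marks <- df[c(seg$ed_phase, seg$es_phase), ]
  marks$label <- c("ED", "ES")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase, y = .data$volume)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = marks, colour = "red", size = 2) +
    ggplot2::geom_text(data = marks, ggplot2::aes(label = .data$label),
                       vjust = -0.8, colour = "red") +
    ggplot2::labs(x = "Cardiac phase", y = "Blood-pool volume (ml)") +
    ggplot2::theme_minimal()
}

#' Mid-ventricular segmentation overlay
#'
#' Raster of one short-axis slice with the two endocardial conventions:
#' papillary/trabecular mask and the smooth compacted-myocardium cavity.
#'
#' @param cine a `cine_stack`.
#' @param seg the matching `lv_segmentation`.
#' @param slice slice index; defaults to the middle of the selected range.
#' @param phase `"ed"` or `"es"`.
#' @return a ggplot object.
#' @export
plot_segmentation_overlay <- function(cine, seg, slice = NULL,
                                      phase = c("ed", "es")) {
  phase <- match.arg(phase)
  if (is.null(slice)) {
    slice <- floor((seg$basal_slice + seg$apical_slice) / 2)
  }
  p_idx <- if (phase == "ed") seg$ed_phase else seg$es_phase
  img <- cine$intensities[p_idx, slice, , ]
  masks <- seg[[phase]]
  grid <- expand.grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  grid$intensity <- as.vector(img)
  grid$pnt <- as.vector(masks$pnt[slice, , ] > 0)
  grid$mex <- as.vector(masks$mex_cavity[slice, , ] > 0)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::stat_contour(ggplot2::aes(z = as.numeric(.data$mex)),
                          breaks = 0.5, colour = "dodgerblue", linewidth = 0.4) +
    ggplot2::stat_contour(ggplot2::aes(z = as.numeric(.data$pnt)),
                          breaks = 0.5, colour = "orange", linewidth = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Slice %d, %s (blue: smooth contour; orange: P&T)",
                                  slice, toupper(phase)),
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Method-difference summary plot
#'
#' Mean within-subject difference between the two conventions per measure and
#' group, with standard-error bars.
#'
#' @param measures tibble from [measure_cohort()].
#' @param vars measures to display.
#' @return a ggplot object.
#' @export
plot_method_differences <- function(measures,
                                    vars = c("lvedv", "lvesv", "lvsv", "lvef",
                                             "lvm")) {
  long <- measures |>
    tidyr::pivot_longer(dplyr::all_of(intersect(vars, names(measures))),
                        names_to = "measure", values_to = "value") |>
    tidyr::pivot_wider(id_cols = c("subject_id", "group", "measure"),
                       names_from = "method", values_from = "value") |>
    dplyr::mutate(diff = .data$minc - .data$mex) |>
    dplyr::group_by(.data$group, .data$measure) |>
    dplyr::summarise(mean = mean(.data$diff),
                     sem = stats::sd(.data$diff) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$measure, y = .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           position = ggplot2::position_dodge(width = 0.8),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = "Mean difference (incl. - excl. P&T)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
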