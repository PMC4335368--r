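#' Pipeline configuration
#'
#' One flat configuration object for the end-to-end run:
#' simulate cohorts, segment, quantify, integrate flow, and summarize.
#'
#' @param n_control,n_fabry cohort sizes.
#' @param seed master seed; all randomness derives from it.
#' @param out_dir output directory for the report bundle.
#' @param seg_config a [segmentation_config()].
#' @param quant a [quant_config()].
#' @param overrides [phantom_spec()] overrides applied to every subject.
#' @param lvm_index_cutoff optional upper limit of normal for indexed LV mass
#'   (g/m^2). When supplied, the bundle reports how many subjects per group
#'   and method exceed it. No default is shipped: published normal ranges
#'   depend on the contouring convention and population, so the cutoff is a
#'   user decision.
#' @param repeatability run the simulated observer-repeatability analysis.
#' @param write_nifti also export per-subject NIfTI series.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_control = 20, n_fabry = 20, seed = 1L,
                            out_dir = NULL,
                            seg_config = segmentation_config(),
                            quant = quant_config(),
                            overrides = list(),
                            lvm_index_cutoff = NULL,
                            repeatability = FALSE,
                            write_nifti = FALSE) {
  structure(list(n_control = n_control, n_fabry = n_fabry,
                 seed = as.integer(seed), out_dir = out_dir,
                 seg_config = seg_config, quant = quant,
                 overrides = overrides,
                 lvm_index_cutoff = lvm_index_cutoff,
                 repeatability = repeatability,
                 write_nifti = write_nifti),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulates a control and a hypertrophic (Fabry-like) cohort, segments every
#' subject with both endocardial conventions, quantifies ventricular
#' measures, integrates aortic flow as the internal stroke-volume reference,
#' and writes a report bundle: per-subject measures (CSV), cohort summary
#' table (CSV + JSON), flow-concordance summary (JSON), optional simulated
#' observer-repeatability Bland-Altman results (JSON), the optional count of
#' subjects exceeding a user-supplied indexed-mass cutoff, and a run log.
#' Identical configuration and seed reproduce the bundle byte-for-byte.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `measures`, `summary`, `flow`, and (if
#'   requested) `repeatability` and `reclassification`, plus `files`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    stop_lvpnt("`config` must come from pipeline_config()", "lvpnt_validation_error")
  }
  out <- config$out_dir
  if (!is.null(out)) {
    ok <- dir.exists(out) || dir.create(out, recursive = TRUE, showWarnings = FALSE)
    if (!ok || file.access(out, 2) != 0) {
      stop_lvpnt(sprintf("output directory '%s' is not writable", out),
                 "lvpnt_validation_error")
    }
  }
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop_lvpnt(sprintf("[%s] %s", what, conditionMessage(e)), "lvpnt_pipeline_error")
    })
  }
  subjects <- stage("simulate", c(
    generate_cohort("control", config$n_control, derive_seed(config$seed, 1L),
                    overrides = config$overrides),
    generate_cohort("fabry", config$n_fabry, derive_seed(config$seed, 2L),
                    overrides = config$overrides)
  ))
  if (length(subjects) == 0L) {
    stop_lvpnt("empty pipeline: both cohort sizes are zero", "lvpnt_validation_error")
  }
  measures <- stage("measure",
                    measure_cohort(subjects, config$seg_config, config$quant))

  have_flow <- "aortic_sv" %in% names(measures) && !all(is.na(measures$aortic_sv))
  both_groups <- length(unique(measures$group)) == 2L
  enough <- all(table(measures$group) >= 4L)
  summary <- if (enough) stage("stats", cohort_table(measures)) else NULL

  flow <- NULL
  if (have_flow && enough) {
    flow <- stage("flow", dplyr::bind_rows(lapply(split(measures, measures$group), function(g) {
      dplyr::bind_rows(flow_concordance(g, "minc"), flow_concordance(g, "mex")) |>
        dplyr::mutate(group = g$group[1], .before = 1)
    })))
  } else if (!have_flow) {
    rlang::warn("no velocity series present: flow-concordance section omitted")
  }

  repeatability <- NULL
  if (config$repeatability) {
    repeatability <- stage("repeatability", lapply(
      split(subjects, vapply(subjects, `[[`, "", "group")),
      observer_repeatability, perturbation_seed = derive_seed(config$seed, 3L),
      seg_config = config$seg_config))
  }

  reclass <- NULL
  if (!is.null(config$lvm_index_cutoff)) {
    reclass <- measures |>
      dplyr::filter(!is.na(.data$lvm_indexed)) |>
      dplyr::group_by(.data$group, .data$method) |>
      dplyr::summarise(n = dplyr::n(),
                       n_above_cutoff = sum(.data$lvm_indexed > config$lvm_index_cutoff),
                       .groups = "drop") |>
      dplyr::mutate(cutoff = config$lvm_index_cutoff)
  }

  files <- character(0)
  if (!is.null(out)) {
    files <- write_bundle(out, config, measures, summary, flow, repeatability, reclass)
    if (config$write_nifti) write_cohort(subjects, file.path(out, "nifti"))
  }
  invisible(list(measures = measures, summary = summary, flow = flow,
                 repeatability = repeatability, reclassification = reclass,
                 subjects = subjects, files = files))
}

write_bundle <- function(out, config, measures, summary, flow, repeatability,
                         reclass) {
  files <- c(subjects = file.path(out, "subject_measures.csv"),
             log = file.path(out, "run_log.txt"))
  utils::write.csv(as.data.frame(measures), files[["subjects"]], row.names = FALSE)
  jprint <- function(x, path) jsonlite::write_json(x, path, auto_unbox = TRUE,
                                                   digits = 10, na = "null")
  if (!is.null(summary)) {
    files[["summary_csv"]] <- file.path(out, "cohort_summary.csv")
    utils::write.csv(as.data.frame(summary$summary), files[["summary_csv"]],
                     row.names = FALSE)
    files[["summary_json"]] <- file.path(out, "cohort_summary.json")
    jprint(lapply(unclass(summary), function(x) if (is.null(x)) NULL else as.data.frame(x)),
           files[["summary_json"]])
  }
  if (!is.null(flow)) {
    files[["flow"]] <- file.path(out, "flow_concordance.json")
    jprint(as.data.frame(flow), files[["flow"]])
  }
  if (!is.null(repeatability)) {
    files[["bland_altman"]] <- file.path(out, "bland_altman.json")
    jprint(lapply(repeatability, function(per_group) {
      lapply(per_group, function(ba) as.list(glance(ba)))
    }), files[["bland_altman"]])
  }
  if (!is.null(reclass)) {
    files[["reclassification"]] <- file.path(out, "lvm_reclassification.json")
    jprint(as.data.frame(reclass), files[["reclassification"]])
  }
  log_lines <- c(
    sprintf("lvpnt pipeline run"),
    sprintf("seed: %d", config$seed),
    sprintf("n_control: %d; n_fabry: %d", config$n_control, config$n_fabry),
    sprintf("segmentation: band %.2f SD; min trabecula %.2f mm; closing %.1f mm",
            config$seg_config$intensity_band_sd,
            config$seg_config$min_trabecula_width,
            config$seg_config$smooth_closing_radius),
    sprintf("quantification: density %.2f g/ml; BSA %s",
            config$quant$myocardial_density, config$quant$bsa_formula),
    sprintf("overrides: %s",
            if (length(config$overrides)) paste(names(config$overrides),
                                                unlist(config$overrides),
                                                sep = "=", collapse = "; ")
            else "none"),
    sprintf("files: %s", paste(basename(files), collapse = ", "))
  )
  writeLines(log_lines, files[["log"]])
  files
}
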