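#' @title End-to-end WMPL and CTV pipeline
#' @description Orchestrates the full flow: load streamlines and masks,
#'   reconcile frames, target the GTV-connected subset, optionally filter
#'   outliers by CCI, densify, compute the WMPL map, build the CTV family
#'   and the comparison report. Every run writes its resolved configuration
#'   and a structured stage log beside the outputs so a run can be
#'   reproduced bit-identically from what it left on disk.
#' @name cli-pipeline
NULL

#' Build a run configuration
#'
#' @param streamlines Path to the input TRK file.
#' @param gtv,brain,recurrence Paths to NIfTI masks (`brain`/`recurrence`
#'   only needed for the CTV stage; `recurrence` optional).
#' @param wmpl Path to a WMPL NIfTI (input of the CTV stage; written by the
#'   WMPL stage).
#' @param out_dir Output directory (created if missing).
#' @param fill Fill value for unvisited voxels (default -1).
#' @param densify_max_step Maximum segment length before path-length
#'   computation; `NULL` (default) means half the smallest voxel size.
#' @param cci_filter Apply CCI outlier filtering before the WMPL stage
#'   (default `FALSE`; the filter is an opt-in stage).
#' @param cci Parameters for [cluster_confidence()] /
#'   [filter_by_cci()]: list with `subsample_n`, `power`, `max_dist`,
#'   `threshold`.
#' @param expansion An [expansion_config()].
#' @param seed Seed recorded with the run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(streamlines = NULL, gtv = NULL, brain = NULL,
                       recurrence = NULL, wmpl = NULL, out_dir = ".",
                       fill = -1, densify_max_step = NULL,
                       cci_filter = FALSE,
                       cci = list(subsample_n = 12L, power = 1, max_dist = 5,
                                  threshold = 1),
                       expansion = expansion_config(), seed = 1L) {
  structure(list(streamlines = streamlines, gtv = gtv, brain = brain,
                 recurrence = recurrence, wmpl = wmpl, out_dir = out_dir,
                 fill = fill, densify_max_step = densify_max_step,
                 cci_filter = isTRUE(cci_filter), cci = cci,
                 expansion = expansion, seed = as.integer(seed)),
            class = "run_config")
}

#' Serialize / restore a run configuration
#'
#' The YAML round trip is stable: writing and re-reading a configuration
#' reproduces it exactly, so re-running from the resolved config written
#' beside the outputs reproduces a run.
#'
#' @param cfg A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns the [run_config()].
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  lst <- unclass(cfg)
  lst$expansion <- unclass(lst$expansion)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  exp_cfg <- do.call(expansion_config, lst$expansion)
  lst$expansion <- NULL
  do.call(run_config, c(lst, list(expansion = exp_cfg)))
}

pipeline_error <- function(stage, input, parent) {
  stop(structure(
    class = c("tractmargin_stage_error", "error", "condition"),
    list(message = sprintf("stage '%s' failed on %s: %s", stage,
                           input %||% "<none>", conditionMessage(parent)),
         call = NULL, stage = stage, parent = parent)))
}

run_stage <- function(stage, input, expr, log) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    if (inherits(e, "tractmargin_stage_error")) stop(e)
    pipeline_error(stage, input, e)
  })
  log$add(stage = stage, seconds = as.numeric(Sys.time() - t0, units = "secs"))
  res
}

make_log <- function() {
  entries <- list()
  list(
    add = function(...) entries[[length(entries) + 1L]] <<- list(...),
    entries = function() entries
  )
}

#' Run the WMPL stage of the pipeline
#'
#' Stages, in order: load streamlines and GTV, reconcile frames, target the
#' GTV-connected subset, optionally CCI-filter, densify, compute the path
#' length map, write `wmpl.nii.gz` (+ JSON sidecar), the resolved config
#' (`run_config.yaml`) and a stage log (`wmpl_log.json`) into `out_dir`.
#' An empty targeted set yields an all-fill map with a warning, not an
#' error.
#'
#' @param cfg A [run_config()] with `streamlines`, `gtv` and `out_dir` set.
#' @return The [path_length_map()], invisibly; side effects on disk.
#' @export
run_wmpl <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  log <- make_log()
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  s <- run_stage("load_streamlines", cfg$streamlines, {
    if (is.null(cfg$streamlines) || !file.exists(cfg$streamlines))
      stop("streamline file not found: ", cfg$streamlines %||% "<missing>")
    read_streamlines(cfg$streamlines)
  }, log)
  gtv <- run_stage("load_gtv", cfg$gtv, {
    if (is.null(cfg$gtv) || !file.exists(cfg$gtv))
      stop("GTV file not found: ", cfg$gtv %||% "<missing>")
    read_volume(cfg$gtv, role = "GTV")
  }, log)
  a <- run_stage("reconcile", cfg$streamlines,
                 reconcile_affine(s$header, gtv), log)
  log$add(stage = "counts", streamlines_in = length(s$polylines),
          gtv_voxels = sum(gtv$values))

  targeted <- run_stage("target", cfg$streamlines,
                        suppressMessages(target_streamlines(s, gtv, a)), log)
  log$add(stage = "target", kept = length(targeted$polylines))

  if (cfg$cci_filter && length(targeted$polylines) >= 2L) {
    targeted <- run_stage("cci_filter", cfg$streamlines, {
      sc <- suppressMessages(cluster_confidence(
        targeted, subsample_n = cfg$cci$subsample_n,
        power = cfg$cci$power, max_dist = cfg$cci$max_dist))
      suppressMessages(filter_by_cci(targeted, sc, cfg$cci$threshold))
    }, log)
    log$add(stage = "cci_filter", kept = length(targeted$polylines))
  }

  max_step <- cfg$densify_max_step %||% (min(gtv$voxel_sizes) / 2)
  dense <- run_stage("densify", cfg$streamlines,
                     densify(targeted, max_step), log)

  w <- run_stage("path_length", cfg$streamlines, {
    if (length(dense$polylines) == 0L) {
      warning("no GTV-connected streamlines: WMPL map is all fill",
              call. = FALSE)
      g <- gtv
      g$values <- array(cfg$fill, dim = gtv$dims)
      class(g) <- "volume_grid"
      attr(g, "role") <- NULL
      path_length_map(g, fill = cfg$fill)
    } else {
      suppressMessages(path_length(dense, gtv, a, fill = cfg$fill))
    }
  }, log)
  log$add(stage = "path_length",
          voxels_visited = sum(w$values != cfg$fill))

  run_stage("write", cfg$out_dir, {
    write_wmpl(w, file.path(cfg$out_dir, "wmpl.nii.gz"))
    write_run_config(cfg, file.path(cfg$out_dir, "run_config.yaml"))
    jsonlite::write_json(log$entries(),
                         file.path(cfg$out_dir, "wmpl_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }, log)
  invisible(w)
}

#' Run the CTV stage of the pipeline
#'
#' Loads the WMPL map, GTV and brain masks, builds one anisotropic CTV per
#' configured EPL plus the isotropic control, writes each mask as NIfTI
#' uint8, a JSON comparison report (`ctv_report.json`) of volumes and
#' recurrence coverage, the resolved config and a stage log.
#'
#' @param cfg A [run_config()] with `wmpl`, `gtv`, `brain` and `out_dir`
#'   set (`recurrence` optional).
#' @return The [build_ctv_set()] result plus `$report`, invisibly.
#' @export
run_ctv <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  log <- make_log()
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  wgrid <- run_stage("load_wmpl", cfg$wmpl, {
    if (is.null(cfg$wmpl) || !file.exists(cfg$wmpl))
      stop("WMPL file not found: ", cfg$wmpl %||% "<missing>")
    g <- read_volume(cfg$wmpl)
    path_length_map(g, fill = cfg$fill)
  }, log)
  gtv <- run_stage("load_gtv", cfg$gtv, read_volume(cfg$gtv, role = "GTV"),
                   log)
  brain <- run_stage("load_brain", cfg$brain,
                     read_volume(cfg$brain, role = "brain"), log)
  rec <- NULL
  if (!is.null(cfg$recurrence))
    rec <- run_stage("load_recurrence", cfg$recurrence,
                     read_volume(cfg$recurrence, role = "recurrence"), log)
  run_stage("align", cfg$wmpl, {
    stop_if_misaligned(wgrid, gtv, "WMPL and GTV grids")
    stop_if_misaligned(wgrid, brain, "WMPL and brain grids")
  }, log)

  ctvs <- run_stage("build_ctvs", cfg$wmpl,
                    build_ctv_set(wgrid, gtv, brain, cfg$expansion), log)

  report <- run_stage("compare", cfg$out_dir, {
    lapply(ctvs$anisotropic, function(m) {
      cmp <- compare_ctvs(m, ctvs$isotropic, rec)
      list(volume_anisotropic_mm3 = cmp$volume_a,
           volume_isotropic_mm3 = cmp$volume_b,
           percent_difference = cmp$percent_difference,
           recurrence_coverage_anisotropic = cmp$coverage_a,
           recurrence_coverage_isotropic = cmp$coverage_b)
    })
  }, log)

  run_stage("write", cfg$out_dir, {
    for (nm in names(ctvs$anisotropic))
      write_volume(ctvs$anisotropic[[nm]],
                   file.path(cfg$out_dir, paste0("ctv_dwmri_", nm, ".nii.gz")))
    write_volume(ctvs$isotropic,
                 file.path(cfg$out_dir, "ctv_isotropic.nii.gz"))
    jsonlite::write_json(report, file.path(cfg$out_dir, "ctv_report.json"),
                         auto_unbox = TRUE, digits = NA)
    write_run_config(cfg, file.path(cfg$out_dir, "run_config.yaml"))
    jsonlite::write_json(log$entries(),
                         file.path(cfg$out_dir, "ctv_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }, log)
  ctvs$report <- report
  invisible(ctvs)
}
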