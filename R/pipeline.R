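#' Build a pipeline configuration
#'
#' Collects every stage's parameters in one object that round-trips
#' losslessly through YAML. Stages can be toggled but always run in the
#' fixed order clean -> register (centre + orient) -> smooth (contour
#' correction) -> reconstruct -> signal.
#'
#' @param input path to a stack manifest (see [load_stack()]).
#' @param output_dir directory for all stage outputs.
#' @param seed integer seed (the pipeline itself is deterministic; the seed
#'   is recorded for provenance and used by phantom generation only).
#' @param clean list: `enabled`, `ranges` (list of `c(Rmin, Rmax, Gmin,
#'   Gmax, Bmin, Bmax)` vectors), `min_tissue_frac`.
#' @param register list: `enabled`, `angular_step`, `metric`.
#' @param smooth list: `enabled`, `angles` (NULL for automatic), `passes`,
#'   `symmetric`.
#' @param reconstruct list: `format` (`"mhd"`, `"nifti"`, `"raw"`),
#'   `measure`, `measure_cavity`, `region` (NULL or x0,x1,y0,y1,z0,z1).
#' @param signal list: `enabled`, `delta`, `reference` (NULL or mm triple),
#'   `overlay_color`.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(input, output_dir, seed = 1L,
                            clean = list(), register = list(),
                            smooth = list(), reconstruct = list(),
                            signal = list()) {
  merge_defaults <- function(given, defaults) {
    for (nm in names(given)) defaults[[nm]] <- given[[nm]]
    defaults
  }
  cfg <- list(
    input = input, output_dir = output_dir, seed = as.integer(seed),
    clean = merge_defaults(clean, list(enabled = TRUE, ranges = list(),
                                       min_tissue_frac = 0.001)),
    register = merge_defaults(register, list(enabled = TRUE,
                                             angular_step = 1,
                                             metric = "l1")),
    smooth = merge_defaults(smooth, list(enabled = TRUE, angles = NULL,
                                         passes = 1L, symmetric = FALSE)),
    reconstruct = merge_defaults(reconstruct,
                                 list(format = "mhd", measure = TRUE,
                                      measure_cavity = FALSE, region = NULL)),
    signal = merge_defaults(signal, list(enabled = FALSE, delta = 40,
                                         reference = NULL,
                                         overlay_color = c(255L, 0L, 0L))))
  # canonical form: NULL-valued keys (angles, region, reference) are omitted
  # so a config survives its YAML form byte-equivalently
  for (st in c("clean", "register", "smooth", "reconstruct", "signal"))
    cfg[[st]] <- cfg[[st]][!vapply(cfg[[st]], is.null, logical(1))]
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration
#'
#' @param path YAML file path.
#' @return `read_config()` returns a `pipeline_config`; `write_config()` the
#'   path, invisibly.
#' @export
read_config <- function(path) {
  m <- yaml::read_yaml(path)
  do.call(pipeline_config,
          m[intersect(names(m), names(formals(pipeline_config)))])
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_ranges <- function(cfg_ranges) {
  lapply(cfg_ranges, function(v) {
    v <- as.integer(unlist(v))
    if (length(v) != 6L)
      stopf("each cleaning range needs 6 values: Rmin,Rmax,Gmin,Gmax,Bmin,Bmax")
    color_range(v[c(1, 3, 5)], v[c(2, 4, 6)])
  })
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the reconstruction pipeline end to end
#'
#' Executes the stages in the fixed order (clean, centre+orient, contour
#' correction, assembly/measurement, signal isolation), writing each stage's
#' outputs and diagnostics under `config$output_dir` and returning the run
#' report. Any stage failure is re-raised with the stage name in the
#' message.
#'
#' @param config a [pipeline_config()].
#' @param stack optional pre-loaded [section_stack()]; when `NULL` the stack
#'   is loaded from `config$input`.
#' @return The report list (also written as `report.json` / `report.txt`);
#'   see [make_report()].
#' @export
run_pipeline <- function(config, stack = NULL) {
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  if (is.null(stack))
    stack <- stage("load", load_stack(config$input))
  artifacts$n_sections <- length(stack$sections)

  if (isTRUE(config$clean$enabled)) {
    ranges <- config_ranges(config$clean$ranges)
    stack <- stage("clean",
                   clean_stack(stack, ranges, config$clean$min_tissue_frac))
    artifacts$excluded_after_clean <- sum(stack_excluded(stack))
  }
  if (isTRUE(config$register$enabled)) {
    reg <- stage("register",
                 register_stack(stack, config$register$angular_step,
                                config$register$metric))
    stack <- reg$stack
    artifacts$registration <- reg$diagnostics
    utils::write.csv(reg$diagnostics,
                     file.path(out, "registration_diagnostics.csv"),
                     row.names = FALSE)
  }
  if (isTRUE(config$smooth$enabled)) {
    sm <- stage("smooth",
                smooth_stack(stack, m = config$smooth$angles,
                             passes = config$smooth$passes,
                             symmetric = isTRUE(config$smooth$symmetric)))
    stack <- sm$stack
  }
  save_stack(stack, file.path(out, "stack"))

  volume <- stage("reconstruct", assemble_volume(stack))
  export_volume(volume, file.path(out, "volume"), config$reconstruct$format)
  artifacts$voxel_dims <- volume$dims
  region <- config$reconstruct$region
  if (!is.null(region)) {
    region <- as.numeric(unlist(region))
    region <- list(x = region[1:2], y = region[3:4], z = region[5:6])
  }
  if (isTRUE(config$reconstruct$measure))
    artifacts$tissue_volume_mm3 <- stage("measure",
                                         measure_volume(volume, region))
  if (isTRUE(config$reconstruct$measure_cavity))
    artifacts$cavity_volume_mm3 <- stage("measure",
                                         measure_cavity_volume(volume, region))

  if (isTRUE(config$signal$enabled)) {
    mask <- stage("signal", isolate_signal(volume, config$signal$delta))
    artifacts$signal <- signal_stats(mask, volume$dims,
                                     config$signal$reference)
    overlay <- overlay_signal(volume, mask, config$signal$overlay_color)
    export_volume(overlay, file.path(out, "overlay"),
                  config$reconstruct$format)
  }
  make_report(artifacts, out)
}

#' Write the run report
#'
#' Emits `report.json` (machine readable) and `report.txt` (human summary)
#' with per-stage counts, exclusions, measured volumes, signal statistics,
#' the package version and the configuration hash. Reports contain no
#' timestamps, so a rerun with the same configuration and inputs is
#' byte-identical.
#'
#' @param artifacts named list of stage outputs (as built by
#'   [run_pipeline()]); must contain at least one stage result.
#' @param out_dir directory for the report files.
#' @return The report list, invisibly.
#' @export
make_report <- function(artifacts, out_dir) {
  if (length(artifacts) <= 1L) stopf("no stage artifacts to report")
  report <- list(
    package_version = as.character(utils::packageVersion("stack3d")),
    config_hash = config_hash(artifacts$config),
    n_sections = artifacts$n_sections,
    excluded_after_clean = artifacts$excluded_after_clean,
    voxel_dims = if (!is.null(artifacts$voxel_dims))
      unclass(artifacts$voxel_dims),
    tissue_volume_mm3 = artifacts$tissue_volume_mm3,
    cavity_volume_mm3 = artifacts$cavity_volume_mm3,
    signal = artifacts$signal)
  report <- report[!vapply(report, is.null, logical(1))]
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  txt <- c(sprintf("stack3d run report (config %s)", report$config_hash),
           sprintf("sections: %d", report$n_sections %||% NA_integer_))
  if (!is.null(report$voxel_dims))
    txt <- c(txt, sprintf("voxel: %.6g x %.6g x %.6g mm",
                          report$voxel_dims$x, report$voxel_dims$y,
                          report$voxel_dims$z))
  txt <- c(txt,
           if (!is.null(report$tissue_volume_mm3))
             sprintf("tissue volume: %.4f mm^3", report$tissue_volume_mm3),
           if (!is.null(report$cavity_volume_mm3))
             sprintf("cavity volume: %.4f mm^3", report$cavity_volume_mm3),
           if (!is.null(report$signal))
             sprintf("signal: %d voxels, %.4f mm^3 (%.2f%% of tissue)",
                     report$signal$count, report$signal$volume_mm3,
                     100 * report$signal$tissue_fraction)
           else "signal: not run")
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(report)
}
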