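#' Pipeline configuration
#'
#' One auditable record of every parameter of the processing sequence.
#' Defaults are the method's standard settings: background opening
#' radius 9, median radius 2, object-smoothing opening radius 2, and a
#' false-positive tolerance of 0.1 percent of pore pixels for the
#' bare-scaffold threshold calibration.
#'
#' @param se_radius structuring-element radius (px) of the background
#'   opening.
#' @param median_radius disk radius (px) of the median filter.
#' @param opening_radius disk radius (px) of the binary opening that
#'   smooths segmented objects.
#' @param reference_slice background reference slice; `NULL` = last.
#' @param roi a [circular_roi()], or `NULL` for automatic fitting.
#' @param tissue_threshold numeric, or `"calibrate"` to calibrate from
#'   a bare-scaffold scan.
#' @param scaffold_threshold low threshold for the dark scaffold class.
#' @param fp_tolerance calibration false-positive tolerance in (0, 1].
#' @param section_boundaries named list of `c(first, last)` ranges, or
#'   `NULL` to split the informative slice range into equal thirds.
#' @param factor_scaffold,factor_tissue mesh resampling factors.
#' @param taubin_lambda,taubin_mu,taubin_iterations smoothing settings.
#' @param make_meshes build surface models (disable for speed when
#'   only the quantification is needed).
#' @param seed recorded in the run log (the pipeline itself is
#'   deterministic).
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(se_radius = 9, median_radius = 2,
                            opening_radius = 2, reference_slice = NULL,
                            roi = NULL, tissue_threshold = "calibrate",
                            scaffold_threshold = 50, fp_tolerance = 0.001,
                            section_boundaries = NULL,
                            factor_scaffold = 1, factor_tissue = 2,
                            taubin_lambda = 0.5, taubin_mu = -0.53,
                            taubin_iterations = 10,
                            make_meshes = TRUE, seed = 1L) {
  if (se_radius < 1 || median_radius < 1 || opening_radius < 0)
    stop("radii must be >= 1 (opening_radius >= 0)")
  if (fp_tolerance <= 0 || fp_tolerance > 1)
    stop("fp_tolerance must lie in (0, 1]")
  if (!identical(tissue_threshold, "calibrate") &&
      !is.numeric(tissue_threshold))
    stop("tissue_threshold must be numeric or \"calibrate\"")
  structure(list(se_radius = se_radius, median_radius = median_radius,
                 opening_radius = opening_radius,
                 reference_slice = reference_slice, roi = roi,
                 tissue_threshold = tissue_threshold,
                 scaffold_threshold = scaffold_threshold,
                 fp_tolerance = fp_tolerance,
                 section_boundaries = section_boundaries,
                 factor_scaffold = factor_scaffold,
                 factor_tissue = factor_tissue,
                 taubin_lambda = taubin_lambda, taubin_mu = taubin_mu,
                 taubin_iterations = taubin_iterations,
                 make_meshes = make_meshes, seed = as.integer(seed)),
            class = "pipeline_config")
}

as_stack <- function(x, what) {
  if (inherits(x, "image_stack")) return(x)
  if (is.character(x) && length(x) == 1) return(read_stack(x))
  stop(what, " must be an image_stack or a TIFF path")
}

## slices that actually contain scaffold: these carry the construct
informative_slices <- function(scaffold_mask, roi_px) {
  px <- apply(scaffold_mask, 3, sum)
  which(px >= 0.01 * roi_px)
}

#' Run the full processing and quantification pipeline
#'
#' Ordered execution of the whole method on one scan: background
#' correction and denoising, ROI fitting, scaffold (dark class) and
#' tissue (bright class) segmentation — with the tissue threshold
#' calibrated against a bare-scaffold scan when requested — per-slice
#' quantification, per-section summaries with ANOVA, 4-stage
#' projections, and smoothed tissue/scaffold surface models. When
#' `output_dir` is given, all intermediates plus a machine-readable
#' run log are written; two runs with identical inputs and
#' configuration produce byte-identical tables.
#'
#' @param sample an [image_stack()] or TIFF path of the cultured scan.
#' @param bare optional bare-scaffold [image_stack()] or path;
#'   required when `tissue_threshold = "calibrate"`.
#' @param config a [pipeline_config()].
#' @param output_dir optional output directory.
#' @return an `mri_pipeline` result bundle.
#' @export
run_pipeline <- function(sample, bare = NULL, config = pipeline_config(),
                         output_dir = NULL) {
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  raw <- stage("read", as_stack(sample, "sample"))
  roi <- stage("roi", fit_roi(raw, roi = config$roi))
  corrected <- stage("correct",
                     correct_stack(raw, config$reference_slice,
                                   config$se_radius, config$median_radius))
  scaffold_mask <- stage("segment-scaffold",
                         segment_scaffold(raw, roi,
                                          config$scaffold_threshold))
  calibrated <- NULL
  thr <- config$tissue_threshold
  if (identical(thr, "calibrate")) {
    if (is.null(bare))
      stop("[calibrate] a bare-scaffold stack is required when ",
           "tissue_threshold = \"calibrate\"")
    bare_raw <- stage("read", as_stack(bare, "bare"))
    bare_roi <- stage("roi", fit_roi(bare_raw, roi = config$roi))
    bare_cor <- stage("correct",
                      correct_stack(bare_raw, config$reference_slice,
                                    config$se_radius, config$median_radius))
    bare_scaf <- stage("segment-scaffold",
                       segment_scaffold(bare_raw, bare_roi,
                                        config$scaffold_threshold))
    thr <- stage("calibrate",
                 calibrate_threshold(bare_cor, bare_roi, bare_scaf,
                                     fp_tolerance = config$fp_tolerance,
                                     opening_radius = config$opening_radius))
    calibrated <- thr
  }
  tissue_mask <- stage("segment-tissue",
                       segment_tissue(corrected, roi, thr,
                                      config$opening_radius))
  masks <- stage("segment", segmentation_masks(
    tissue_mask, scaffold_mask, roi,
    tissue_threshold = thr,
    scaffold_threshold = config$scaffold_threshold))
  stopifnot(!any(masks$tissue_mask & masks$scaffold_mask))
  records <- stage("quantify", quantify_stack(masks))
  boundaries <- config$section_boundaries
  if (is.null(boundaries)) {
    inf <- informative_slices(masks$scaffold_mask, sum(masks$roi_mask))
    boundaries <- if (length(inf) >= 3)
      split_sections(min(inf), max(inf)) else NULL
  }
  summaries <- anova <- NULL
  projections <- list()
  if (!is.null(boundaries)) {
    summaries <- stage("quantify", summarize_sections(records, boundaries))
    if (all(vapply(boundaries, function(b) diff(b) >= 1, logical(1))))
      anova <- stage("quantify", compare_sections(records, boundaries))
    projections <- lapply(boundaries, function(b)
      stage_projection(masks$tissue_mask[, , b[1]:b[2], drop = FALSE]))
  }
  scene <- NULL
  if (isTRUE(config$make_meshes)) {
    sp <- c(raw$pixel_size, raw$pixel_size, raw$slice_thickness)
    tm <- stage("mesh", taubin_smooth(
      marching_cubes(masks$tissue_mask, config$factor_tissue, sp,
                     label = "tissue"),
      config$taubin_lambda, config$taubin_mu, config$taubin_iterations))
    sm <- stage("mesh", taubin_smooth(
      marching_cubes(masks$scaffold_mask, config$factor_scaffold, sp,
                     label = "scaffold"),
      config$taubin_lambda, config$taubin_mu, config$taubin_iterations))
    scene <- stage("mesh", assemble_model(tm, sm))
  }
  res <- structure(list(roi = roi, corrected = corrected, masks = masks,
                        records = records, boundaries = boundaries,
                        summaries = summaries, anova = anova,
                        projections = projections, scene = scene,
                        tissue_threshold = thr,
                        calibrated_threshold = calibrated,
                        config = config),
                   class = "mri_pipeline")
  if (!is.null(output_dir))
    res$files <- stage("write", write_pipeline_outputs(
      res, output_dir,
      sample_path = if (is.character(sample)) sample else NULL,
      bare_path = if (is.character(bare)) bare else NULL))
  res
}

#' @export
print.mri_pipeline <- function(x, ...) {
  cat("mri_pipeline result\n")
  print(x$roi)
  cat(sprintf("  tissue threshold %.6g%s, scaffold threshold %.6g\n",
              x$tissue_threshold,
              if (!is.null(x$calibrated_threshold)) " (calibrated)" else "",
              x$config$scaffold_threshold))
  if (!is.null(x$summaries)) {
    cat("  tissue %% of available pore volume per section:\n")
    print(x$summaries, row.names = FALSE)
  }
  if (!is.null(x$anova)) print(x$anova)
  invisible(x)
}

write_pipeline_outputs <- function(res, output_dir, sample_path = NULL,
                                   bare_path = NULL) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(output_dir, ...)
  files <- c(corrected = p("corrected.tif"),
             tissue_mask = p("tissue_mask.tif"),
             scaffold_mask = p("scaffold_mask.tif"),
             quant = p("quantification.csv"),
             log = p("run_log.json"))
  write_stack(res$corrected, files["corrected"])
  write_mask(res$masks$tissue_mask, files["tissue_mask"])
  write_mask(res$masks$scaffold_mask, files["scaffold_mask"])
  write_quant_csv(res$records, files["quant"], res$summaries)
  if (!is.null(res$summaries)) {
    files["sections"] <- p("sections.csv")
    utils::write.csv(res$summaries, files["sections"], row.names = FALSE)
  }
  for (nm in names(res$projections)) {
    f <- p(paste0("projection_", nm, ".png"))
    write_projection_png(res$projections[[nm]], f)
    files[paste0("projection_", nm)] <- f
  }
  if (!is.null(res$scene)) {
    for (nm in names(res$scene$objects)) {
      f <- p(paste0(nm, ".ply"))
      write_ply(res$scene$objects[[nm]], f)
      files[paste0("mesh_", nm)] <- f
    }
    files["scene"] <- p("model.obj")
    write_scene_obj(res$scene, files["scene"])
  }
  cfg <- res$config
  cfg$roi <- if (is.null(cfg$roi)) NULL else unclass(cfg$roi)
  log <- list(
    config = unclass(cfg),
    inputs = list(
      sample = sample_path, bare = bare_path,
      sample_md5 = if (!is.null(sample_path))
        unname(tools::md5sum(sample_path)) else NULL,
      bare_md5 = if (!is.null(bare_path))
        unname(tools::md5sum(bare_path)) else NULL),
    roi = unclass(res$roi),
    tissue_threshold = res$tissue_threshold,
    scaffold_threshold = res$config$scaffold_threshold,
    boundaries = res$boundaries)
  jsonlite::write_json(log, files["log"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  files
}

#' Re-run a pipeline from a stored run log
#'
#' Reads the machine-readable run log of a previous run and executes
#' the pipeline again with the recorded configuration and inputs,
#' reproducing all numeric outputs exactly.
#'
#' @param log_path path to a `run_log.json`.
#' @param output_dir optional output directory for the replay.
#' @return an `mri_pipeline` result bundle.
#' @export
replay_run <- function(log_path, output_dir = NULL) {
  log <- jsonlite::read_json(log_path, simplifyVector = TRUE)
  cfg <- log$config
  cfg$roi <- if (is.null(cfg$roi)) NULL else
    circular_roi(cfg$roi$center_x, cfg$roi$center_y, cfg$roi$radius)
  cfg$reference_slice <- if (is.null(cfg$reference_slice)) NULL else
    cfg$reference_slice
  bounds <- if (is.null(cfg$section_boundaries) ||
                length(cfg$section_boundaries) == 0) NULL else
    lapply(cfg$section_boundaries, as.numeric)
  config <- pipeline_config(
    se_radius = cfg$se_radius, median_radius = cfg$median_radius,
    opening_radius = cfg$opening_radius,
    reference_slice = cfg$reference_slice, roi = cfg$roi,
    tissue_threshold = cfg$tissue_threshold,
    scaffold_threshold = cfg$scaffold_threshold,
    fp_tolerance = cfg$fp_tolerance, section_boundaries = bounds,
    factor_scaffold = cfg$factor_scaffold,
    factor_tissue = cfg$factor_tissue,
    taubin_lambda = cfg$taubin_lambda, taubin_mu = cfg$taubin_mu,
    taubin_iterations = cfg$taubin_iterations,
    make_meshes = cfg$make_meshes, seed = cfg$seed)
  if (is.null(log$inputs$sample))
    stop("run log does not record an input path to replay")
  run_pipeline(log$inputs$sample, bare = log$inputs$bare, config = config,
               output_dir = output_dir)
}
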