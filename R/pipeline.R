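#' Pipeline configuration
#'
#' Flat configuration for the end-to-end pipeline; defaults reproduce the
#' reference settings (0.7 x 0.7 x 2.5 mm grid, 2 cm^2 ROI, 2 cm offset, 3
#' slices 0.5 cm apart, 40 HU threshold, 1000 bootstrap replicates). It can
#' be round-tripped through a flat YAML file with [read_config()] /
#' [write_config()]; unknown keys in a config file are an error.
#'
#' @param target_spacing_mm resampling target, length 3.
#' @param roi_area_mm2,roi_center_offset_mm,roi_n_slices,roi_min_axial_separation_mm,roi_clip_to_mask
#'   ROI geometry, see [roi_params()].
#' @param threshold_hu steatosis decision threshold.
#' @param n_boot,seed bootstrap settings for the statistics layer.
#' @param resample whether to resample inputs to `target_spacing_mm`.
#' @param keep_largest_component whether to reduce the mask to its largest
#'   connected component before measurement.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(target_spacing_mm = c(0.7, 0.7, 2.5),
                            roi_area_mm2 = 200,
                            roi_center_offset_mm = 20,
                            roi_n_slices = 3L,
                            roi_min_axial_separation_mm = 5,
                            roi_clip_to_mask = FALSE,
                            threshold_hu = 40,
                            n_boot = 1000L,
                            seed = 17L,
                            resample = TRUE,
                            keep_largest_component = TRUE) {
  cfg <- list(target_spacing_mm = as.numeric(target_spacing_mm),
              roi_area_mm2 = roi_area_mm2,
              roi_center_offset_mm = roi_center_offset_mm,
              roi_n_slices = as.integer(roi_n_slices),
              roi_min_axial_separation_mm = roi_min_axial_separation_mm,
              roi_clip_to_mask = isTRUE(roi_clip_to_mask),
              threshold_hu = threshold_hu,
              n_boot = as.integer(n_boot),
              seed = as.integer(seed),
              resample = isTRUE(resample),
              keep_largest_component = isTRUE(keep_largest_component))
  check_spacing(cfg$target_spacing_mm)
  # validate ROI fields eagerly
  as_roi_params(cfg)
  structure(cfg, class = "pipeline_config")
}

as_roi_params <- function(cfg) {
  roi_params(roi_area_mm2 = cfg$roi_area_mm2,
             center_offset_mm = cfg$roi_center_offset_mm,
             n_slices = cfg$roi_n_slices,
             min_axial_separation_mm = cfg$roi_min_axial_separation_mm,
             clip_to_mask = cfg$roi_clip_to_mask)
}

#' @rdname pipeline_config
#' @param path path of a flat YAML config file.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full measurement pipeline on one CT/mask pair
#'
#' Reads the NIfTI pair, canonicalizes orientation, optionally resamples to
#' the target grid and reduces the mask to its largest connected component,
#' computes all three attenuation estimators, and categorizes steatosis from
#' the parenchymal value. Deterministic for fixed inputs and config.
#'
#' @param ct_path,mask_path NIfTI file paths (the mask on the same grid as
#'   the CT).
#' @param config a [pipeline_config()].
#' @param case_id identifier used in the report (defaults to the CT
#'   filename).
#' @return A `case_report` list: `case_id`, `volumetric_hu`, `axial_hu`,
#'   `parenchymal_hu`, `category`, `threshold_hu`, `rois` (placement
#'   geometry), `warnings`.
#' @export
run_pipeline <- function(ct_path, mask_path, config = pipeline_config(),
                         case_id = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(case_id))
    case_id <- sub("\\.nii(\\.gz)?$", "", basename(ct_path))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("case ", case_id, ", stage ", name, ": ", conditionMessage(e),
           call. = FALSE))
  }
  ct <- stage("read", read_volume(ct_path))
  mask <- stage("read", read_mask(mask_path))
  ct <- stage("canonicalize", canonicalize(ct))
  mask <- stage("canonicalize", canonicalize(mask))
  if (config$resample) {
    ct <- stage("resample", resample(ct, config$target_spacing_mm))
    mask <- stage("resample", resample(mask, config$target_spacing_mm))
  }
  if (config$keep_largest_component)
    mask <- stage("largest_component", largest_component(mask))
  vol <- stage("measure_volumetric", measure_volumetric(ct, mask))
  axi <- stage("measure_axial", measure_axial(ct, mask))
  par <- stage("measure_parenchymal",
               measure_parenchymal(ct, mask, as_roi_params(config)))
  structure(list(
    case_id = case_id,
    volumetric_hu = vol$value_hu,
    axial_hu = axi$value_hu,
    axial_slice = axi$slice_index,
    parenchymal_hu = par$value_hu,
    category = classify_steatosis(par$value_hu, config$threshold_hu),
    threshold_hu = config$threshold_hu,
    rois = lapply(par$rois, function(r)
      list(slice = r$slice, center = as.integer(r$center),
           radius_mm = r$radius_mm, mean_hu = r$mean_hu,
           in_mask_fraction = r$in_mask_fraction)),
    warnings = par$warnings), class = "case_report")
}

#' @export
print.case_report <- function(x, ...) {
  cat("<case_report> ", x$case_id, "\n", sep = "")
  cat(sprintf("  volumetric: %8.2f HU\n", x$volumetric_hu))
  cat(sprintf("  axial:      %8.2f HU (slice %d)\n", x$axial_hu,
              x$axial_slice))
  cat(sprintf("  parenchymal:%8.2f HU (%d ROIs)\n", x$parenchymal_hu,
              length(x$rois)))
  cat("  category:   ", x$category, " (threshold ", x$threshold_hu,
      " HU)\n", sep = "")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Write a case report as JSON
#'
#' @param report a `case_report` from [run_pipeline()].
#' @param path output JSON path.
#' @export
write_case_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Batch-run the pipeline over many CT/mask pairs
#'
#' @param cases data.frame with columns `case_id`, `ct_path`, `mask_path`.
#' @param config a [pipeline_config()].
#' @param csv_path optional path; when given, the summary table is written
#'   as CSV.
#' @return data.frame with one row per case: `case_id`, `volumetric_hu`,
#'   `axial_hu`, `parenchymal_hu`, `category`.
#' @export
run_batch <- function(cases, config = pipeline_config(), csv_path = NULL) {
  stopifnot(all(c("case_id", "ct_path", "mask_path") %in% names(cases)))
  rows <- lapply(seq_len(nrow(cases)), function(i) {
    rep <- run_pipeline(cases$ct_path[i], cases$mask_path[i], config,
                        case_id = cases$case_id[i])
    data.frame(case_id = rep$case_id, volumetric_hu = rep$volumetric_hu,
               axial_hu = rep$axial_hu, parenchymal_hu = rep$parenchymal_hu,
               category = rep$category)
  })
  out <- do.call(rbind, rows)
  if (!is.null(csv_path)) write.csv(out, csv_path, row.names = FALSE)
  out
}

#' Read paired attenuation readings and labels from CSV
#'
#' `read_readings` expects columns `case_id`, `method`, `value_hu` (long
#' format, one row per case and method); `read_labels` expects `case_id`
#' and `steatosis` (0/1).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_readings <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "method", "value_hu")
  if (!all(need %in% names(df)))
    stop("readings CSV must have columns ", paste(need, collapse = ", "))
  df
}

#' @rdname read_readings
#' @export
read_labels <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("case_id", "steatosis") %in% names(df)))
    stop("labels CSV must have columns case_id, steatosis")
  df
}

#' Pair two methods out of a long readings table
#'
#' @param readings data.frame as from [read_readings()].
#' @param method,reference names of the two methods to pair.
#' @return data.frame with `case_id`, `method_hu`, `reference_hu` for cases
#'   measured by both.
#' @export
pair_readings <- function(readings, method, reference) {
  a <- readings[readings$method == method, c("case_id", "value_hu")]
  b <- readings[readings$method == reference, c("case_id", "value_hu")]
  m <- merge(a, b, by = "case_id", suffixes = c("_method", "_reference"))
  if (nrow(m) < 2L) stop("fewer than 2 cases shared by both methods")
  data.frame(case_id = m$case_id, method_hu = m$value_hu_method,
             reference_hu = m$value_hu_reference)
}
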