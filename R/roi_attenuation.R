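#' Parameters of the parenchymal ROI procedure
#'
#' Geometry of the automated circular ROI placement used by the parenchymal
#' attenuation estimator: on each of the `n_slices` largest axial slices of
#' the liver mask (subject to a minimum axial separation), one circular ROI
#' of `roi_area_mm2` is centered `center_offset_mm` to the patient-left of
#' that slice's leftmost mask pixel. Placing the ROI near the lateral margin
#' of the right hepatic lobe samples clean parenchyma, since vessels and
#' bile ducts concentrate toward the liver center; the 2 cm offset leaves
#' roughly 1 cm between the ROI rim and the liver contour at the default
#' 2 cm^2 area (radius ~7.98 mm).
#'
#' @param roi_area_mm2 ROI disc area in mm^2 (default 200, i.e. 2 cm^2).
#' @param center_offset_mm distance from the leftmost mask pixel to the ROI
#'   center along the patient-left axis (default 20, i.e. 2 cm).
#' @param n_slices number of ROI-bearing slices (default 3).
#' @param min_axial_separation_mm minimum axial distance between any two
#'   selected slices (default 5, i.e. 0.5 cm).
#' @param clip_to_mask if `TRUE`, ROI means use only pixels inside the mask;
#'   by default the full disc is averaged, as a manually drawn circular ROI
#'   would be.
#' @param min_in_mask_fraction_warn warn when the fraction of ROI pixels
#'   inside the mask falls below this value (default 0.9).
#' @return A `roi_params` object.
#' @export
roi_params <- function(roi_area_mm2 = 200, center_offset_mm = 20,
                       n_slices = 3L, min_axial_separation_mm = 5,
                       clip_to_mask = FALSE,
                       min_in_mask_fraction_warn = 0.9) {
  if (roi_area_mm2 <= 0 || center_offset_mm <= 0 ||
      min_axial_separation_mm <= 0)
    stop("ROI lengths and areas must be positive")
  n_slices <- as.integer(n_slices)
  if (n_slices < 1L) stop("n_slices must be >= 1")
  structure(list(roi_area_mm2 = roi_area_mm2,
                 center_offset_mm = center_offset_mm,
                 n_slices = n_slices,
                 min_axial_separation_mm = min_axial_separation_mm,
                 clip_to_mask = isTRUE(clip_to_mask),
                 min_in_mask_fraction_warn = min_in_mask_fraction_warn,
                 radius_mm = sqrt(roi_area_mm2 / pi)),
            class = "roi_params")
}

require_canonical <- function(x, what) {
  if (!identical(x$orientation, "LPS"))
    stop(what, " must be in canonical LPS orientation; call canonicalize()")
  invisible(TRUE)
}

attenuation_result <- function(method, value_hu, rois = NULL,
                               slice_index = NULL, warnings = character()) {
  structure(list(method = method, value_hu = value_hu, rois = rois,
                 slice_index = slice_index, warnings = warnings),
            class = "attenuation_result")
}

#' @export
print.attenuation_result <- function(x, ...) {
  cat("<attenuation_result> method = ", x$method, ", value = ",
      format(round(x$value_hu, 2), nsmall = 2), " HU\n", sep = "")
  if (!is.null(x$slice_index))
    cat("  largest axial slice:", x$slice_index, "\n")
  if (!is.null(x$rois))
    cat("  ROIs on slices:",
        paste(vapply(x$rois, `[[`, integer(1), "slice"), collapse = ", "),
        "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Volumetric attenuation: mean HU over the whole segmentation
#'
#' The simplest estimator: the arithmetic mean of all CT voxels under the
#' liver mask. It is biased upward by hyperattenuating non-parenchymal
#' structures (vessels, bile ducts) included in the segmentation.
#'
#' @param ct a [ct_volume()].
#' @param mask a nonempty [binary_mask()] on the same grid.
#' @return An `attenuation_result` with `method = "volumetric"`.
#' @export
measure_volumetric <- function(ct, mask) {
  check_same_geometry(ct, mask)
  if (!any(mask$data)) stop("empty mask")
  attenuation_result("volumetric", mean(ct$data[mask$data]))
}

#' Axial attenuation: mean HU over the largest axial slice
#'
#' Mean CT value over the mask pixels of the single axial slice with the
#' largest cross-sectional segmentation area. Area ties are broken in favor
#' of the lowest (most inferior) slice index.
#'
#' @inheritParams measure_volumetric
#' @return An `attenuation_result` with `method = "axial"` and the selected
#'   `slice_index`.
#' @export
measure_axial <- function(ct, mask) {
  check_same_geometry(ct, mask)
  require_canonical(mask, "mask")
  prof <- slice_area_profile(mask)
  if (nrow(prof) == 0L) stop("empty mask")
  best <- prof$slice[which.max(prof$area_mm2)]  # which.max: first = lowest
  sl_mask <- mask$data[, , best]
  attenuation_result("axial", mean(ct$data[, , best][sl_mask]),
                     slice_index = best)
}

#' Place circular parenchymal ROIs on the largest axial slices
#'
#' Implements the automated ROI geometry of the parenchymal estimator:
#'
#' 1. Axial slices are ranked by in-mask area and selected greedily (largest
#'    first) subject to a pairwise axial separation of at least
#'    `min_axial_separation_mm`, until `n_slices` slices are chosen. Equal
#'    areas favor the lower slice index.
#' 2. On each selected slice, the leftmost mask pixel is found (minimum
#'    index along the patient-left axis); among rows attaining it the lower
#'    median row is taken. The ROI center is `center_offset_mm` to the
#'    patient-left of that pixel (rounded to the nearest pixel).
#' 3. ROI member pixels are all pixels whose centers lie within
#'    `radius_mm = sqrt(roi_area_mm2 / pi)` of the center in physical mm.
#'
#' If fewer than `n_slices` slices can be selected, the feasible ROIs are
#' returned with a warning. An ROI disc extending beyond the image grid is
#' an error naming the slice.
#'
#' @param mask a nonempty [binary_mask()] in canonical orientation, on the
#'   measurement grid (default 0.7 x 0.7 x 2.5 mm).
#' @param params a [roi_params()].
#' @return A list of ROI placements, each a list with `slice`, `center`
#'   (in-plane voxel indices), `radius_mm`, `pixels` (two-column index
#'   matrix) and `in_mask_fraction`; the character vector of warnings is
#'   attached as attribute `"warnings"`.
#' @export
select_parenchymal_rois <- function(mask, params = roi_params()) {
  stopifnot(inherits(params, "roi_params"))
  require_canonical(mask, "mask")
  prof <- slice_area_profile(mask)
  if (nrow(prof) == 0L) stop("empty mask")
  warns <- character()

  ord <- prof[order(-prof$area_mm2, prof$slice), ]
  sp <- mask$spacing_mm
  chosen <- integer()
  for (s in ord$slice) {
    if (length(chosen) >= params$n_slices) break
    if (all(abs(s - chosen) * sp[3] >= params$min_axial_separation_mm - 1e-9))
      chosen <- c(chosen, s)
  }
  if (length(chosen) < params$n_slices) {
    warns <- c(warns, sprintf(
      "only %d of %d requested ROI slices satisfiable", length(chosen),
      params$n_slices))
  }
  chosen <- sort(chosen)

  d <- dim(mask$data)
  r <- params$radius_mm
  rois <- lapply(chosen, function(s) {
    pix <- which(mask$data[, , s], arr.ind = TRUE)
    leftmost <- min(pix[, 1])
    rows <- sort(pix[pix[, 1] == leftmost, 2])
    center_row <- rows[floor((length(rows) + 1) / 2)]  # lower median
    center_i <- leftmost + round(params$center_offset_mm / sp[1])
    ri <- ceiling(r / sp[1]); rj <- ceiling(r / sp[2])
    ii <- (center_i - ri):(center_i + ri)
    jj <- (center_row - rj):(center_row + rj)
    g <- expand.grid(i = ii, j = jj)
    inside <- ((g$i - center_i) * sp[1])^2 + ((g$j - center_row) * sp[2])^2 <=
      r^2 + 1e-9
    g <- g[inside, , drop = FALSE]
    if (any(g$i < 1 | g$i > d[1] | g$j < 1 | g$j > d[2]))
      stop("ROI extends beyond the image grid on slice ", s)
    in_mask <- mask$data[cbind(g$i, g$j, s)]
    list(slice = s, center = unname(c(center_i, center_row)), radius_mm = r,
         pixels = cbind(i = g$i, j = g$j),
         in_mask_fraction = mean(in_mask))
  })
  low <- vapply(rois, `[[`, numeric(1), "in_mask_fraction") <
    params$min_in_mask_fraction_warn
  if (any(low)) {
    warns <- c(warns, sprintf(
      "ROI on slice %s has in-mask fraction below %.2f",
      paste(chosen[low], collapse = ", "), params$min_in_mask_fraction_warn))
  }
  for (w in warns) warning(w, call. = FALSE)
  attr(rois, "warnings") <- warns
  rois
}

#' Parenchymal attenuation: mean HU over automatically placed ROIs
#'
#' Places circular ROIs with [select_parenchymal_rois()] and reports the
#' unweighted mean of the per-ROI mean HU values, mirroring how a reader's
#' independent circular ROI measurements are averaged. By default the full
#' disc is averaged; with `clip_to_mask` in `params`, pixels outside the
#' mask are excluded.
#'
#' @inheritParams measure_volumetric
#' @param params a [roi_params()].
#' @return An `attenuation_result` with `method = "parenchymal"`, the ROI
#'   placements (with per-ROI `mean_hu` filled in), and any placement
#'   warnings.
#' @export
measure_parenchymal <- function(ct, mask, params = roi_params()) {
  check_same_geometry(ct, mask)
  rois <- withCallingHandlers(
    select_parenchymal_rois(mask, params),
    warning = function(w) invokeRestart("muffleWarning"))
  if (length(rois) == 0L) stop("no placeable ROI")
  warns <- attr(rois, "warnings") %||% character()
  rois <- lapply(rois, function(roi) {
    px <- roi$pixels
    if (params$clip_to_mask) {
      keep <- mask$data[cbind(px[, 1], px[, 2], roi$slice)]
      if (!any(keep))
        stop("ROI on slice ", roi$slice, " has no pixels inside the mask")
      px <- px[keep, , drop = FALSE]
    }
    roi$mean_hu <- mean(ct$data[cbind(px[, 1], px[, 2], roi$slice)])
    roi
  })
  attenuation_result("parenchymal",
                     mean(vapply(rois, `[[`, numeric(1), "mean_hu")),
                     rois = rois, warnings = warns)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Categorize moderate-to-severe hepatic steatosis from attenuation
#'
#' A liver with mean attenuation strictly below the threshold (default
#' 40 HU) is categorized as moderate-to-severe steatosis; exactly 40 HU is
#' `"normal"` (the inequality is strict).
#'
#' @param attenuation_hu numeric vector of attenuation values in HU.
#' @param threshold_hu decision threshold, default 40.
#' @return Character vector, `"steatosis"` or `"normal"` per value.
#' @examples
#' classify_steatosis(c(39.9, 40, 56.33))
#' @export
classify_steatosis <- function(attenuation_hu, threshold_hu = 40) {
  if (inherits(attenuation_hu, "attenuation_result"))
    attenuation_hu <- attenuation_hu$value_hu
  if (any(!is.finite(attenuation_hu)))
    stop("attenuation must be finite")
  ifelse(attenuation_hu < threshold_hu, "steatosis", "normal")
}
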