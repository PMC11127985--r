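#' Overlap metrics between two binary masks
#'
#' Dice similarity coefficient `2|P&R| / (|P|+|R|)` and Jaccard coefficient
#' `|P&R| / (|P|+|R|-|P&R|)` between a predicted and a reference mask on the same
#' grid. The two are linked by `jc = dsc / (2 - dsc)`.
#'
#' @param pred,ref [binary_mask()] objects on the same grid; `ref` nonempty.
#' @return A list with `dsc` and `jc`.
#' @export
overlap_metrics <- function(pred, ref) {
  check_same_geometry(pred, ref)
  np <- sum(pred$data); nr <- sum(ref$data)
  if (np == 0L && nr == 0L) stop("both masks are empty")
  if (nr == 0L) stop("reference mask is empty")
  inter <- sum(pred$data & ref$data)
  list(dsc = 2 * inter / (np + nr), jc = inter / (np + nr - inter))
}

# voxels of the mask with at least one 6-neighbor outside the mask
# (volume borders count as outside); returned as an n x 3 index matrix
surface_voxels <- function(mask) {
  interior <- erode6(mask$data)
  which(mask$data & !interior, arr.ind = TRUE)
}

#' Surface distance metrics between two binary masks
#'
#' Surfaces are the mask voxels with at least one non-mask 6-neighbor;
#' distances are Euclidean between surface-voxel centers in physical mm,
#' honoring anisotropic spacing. The Hausdorff distance is the exact maximum
#' over both directed maxima (no percentile variant); the average symmetric
#' surface distance is the pooled mean of all directed nearest-surface
#' distances from both surfaces, i.e. weighted by surface size.
#'
#' @param pred,ref nonempty [binary_mask()] objects on the same grid.
#' @return A list with `hd_mm` and `assd_mm`.
#' @export
surface_metrics <- function(pred, ref) {
  check_same_geometry(pred, ref)
  if (!any(pred$data)) stop("predicted mask is empty; distances undefined")
  if (!any(ref$data)) stop("reference mask is empty; distances undefined")
  sp <- pred$spacing_mm
  a <- sweep(surface_voxels(pred) - 1, 2, sp, `*`)
  b <- sweep(surface_voxels(ref) - 1, 2, sp, `*`)
  d_ab <- cpp_nn_dists(a, b)
  d_ba <- cpp_nn_dists(b, a)
  list(hd_mm = max(max(d_ab), max(d_ba)),
       assd_mm = (sum(d_ab) + sum(d_ba)) / (length(d_ab) + length(d_ba)))
}

#' All segmentation accuracy metrics at once
#'
#' @inheritParams surface_metrics
#' @return A list with `dsc`, `jc`, `hd_mm`, `assd_mm`.
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(64, 56, 16),
#'                                     liver_semiaxes_mm = c(18, 15, 14),
#'                                     seed = 2))
#' ref <- ph$truth$liver_mask
#' seg_metrics(perturb_mask(ref, "erode", 1), ref)
#' @export
seg_metrics <- function(pred, ref) {
  c(overlap_metrics(pred, ref), surface_metrics(pred, ref))
}
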