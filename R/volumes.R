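#' CT volume and binary mask containers
#'
#' A `ct_volume` holds a 3D scalar grid of Hounsfield units together with its
#' voxel spacing in mm and an anatomical orientation tag. A `binary_mask`
#' holds a logical grid with the same geometry metadata (typically a liver
#' segmentation on the grid of its paired CT).
#'
#' The orientation tag is a three-letter string, one letter per array axis,
#' giving the anatomical direction in which that axis *increases*: `R`/`L`
#' (patient right/left), `A`/`P` (anterior/posterior), `S`/`I`
#' (superior/inferior). The canonical orientation used throughout the package
#' is `"LPS"`: axis 1 increases toward patient-left, axis 2 toward posterior,
#' axis 3 toward superior, so axial slices are the third-axis planes and the
#' patient's lateral right hepatic lobe sits at low axis-1 indices.
#'
#' Voxels are treated as point samples at their centers; all physical
#' distances are computed between voxel centers. Indices are 1-based as usual
#' in R; the center of voxel `i` along an axis lies at `(i - 1) * spacing`.
#'
#' @param data 3D numeric array (HU) for `ct_volume`; anything coercible to
#'   logical (e.g. a 0/1 array) for `binary_mask`.
#' @param spacing_mm numeric length-3, strictly positive voxel spacing in mm.
#' @param orientation three-letter orientation string, default `"LPS"`.
#' @return An object of class `ct_volume` or `binary_mask`.
#' @examples
#' vol <- ct_volume(array(60, dim = c(4, 4, 2)), spacing_mm = c(0.7, 0.7, 2.5))
#' vol$spacing_mm
#' @export
ct_volume <- function(data, spacing_mm = c(0.7, 0.7, 2.5), orientation = "LPS") {
  data <- unclass(data)
  attributes(data) <- list(dim = dim(data))
  if (length(dim(data)) != 3L)
    stop("ct_volume requires a 3D array, got ", length(dim(data)), " dimensions")
  check_spacing(spacing_mm)
  check_orientation(orientation)
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm),
                 orientation = orientation),
            class = "ct_volume")
}

#' @rdname ct_volume
#' @export
binary_mask <- function(data, spacing_mm = c(0.7, 0.7, 2.5), orientation = "LPS") {
  d <- dim(data)
  if (length(d) != 3L)
    stop("binary_mask requires a 3D array, got ", length(d), " dimensions")
  data <- as.logical(data > 0.5)
  dim(data) <- d
  check_spacing(spacing_mm)
  check_orientation(orientation)
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm),
                 orientation = orientation),
            class = "binary_mask")
}

check_spacing <- function(spacing_mm) {
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("spacing_mm must be three strictly positive finite values")
  invisible(spacing_mm)
}

.axis_letters <- list(c("R", "L"), c("A", "P"), c("S", "I"))

check_orientation <- function(orientation) {
  if (!is.character(orientation) || length(orientation) != 1L ||
      nchar(orientation) != 3L)
    stop("orientation must be a three-letter string such as \"LPS\"")
  letters3 <- strsplit(orientation, "")[[1]]
  world <- vapply(letters3, function(l) {
    w <- which(vapply(.axis_letters, function(p) l %in% p, logical(1)))
    if (length(w) != 1L) stop("unrecognized orientation letter: ", l)
    w
  }, numeric(1))
  if (anyDuplicated(world))
    stop("orientation \"", orientation,
         "\" does not name three distinct anatomical axes")
  invisible(orientation)
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing_mm), collapse = " x "),
      " mm, orientation ", x$orientation, "\n", sep = "")
  cat("  HU range: [", format(min(x$data)), ", ", format(max(x$data)), "]\n",
      sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing_mm), collapse = " x "),
      " mm, orientation ", x$orientation, ", ",
      sum(x$data), " foreground voxels\n", sep = "")
  invisible(x)
}

#' Check that two grids share shape, spacing and orientation
#'
#' Measurements pair a CT with a mask; both must live on the same grid.
#' @param a,b `ct_volume` or `binary_mask` objects.
#' @return Invisibly `TRUE`; errors if the geometries differ.
#' @export
check_same_geometry <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("geometry mismatch: shapes ", paste(dim(a$data), collapse = "x"),
         " vs ", paste(dim(b$data), collapse = "x"))
  if (max(abs(a$spacing_mm - b$spacing_mm)) > 1e-6)
    stop("geometry mismatch: spacings differ")
  if (!identical(a$orientation, b$orientation))
    stop("geometry mismatch: orientations ", a$orientation, " vs ",
         b$orientation)
  invisible(TRUE)
}

orientation_from_affine <- function(affine) {
  codes <- character(3)
  world_axes <- integer(3)
  for (j in 1:3) {
    col <- affine[1:3, j]
    if (all(abs(col) < 1e-12))
      stop("degenerate affine: zero column for voxel axis ", j)
    k <- which.max(abs(col))
    world_axes[j] <- k
    codes[j] <- .axis_letters[[k]][if (col[k] > 0) 1L else 2L]
  }
  if (anyDuplicated(world_axes))
    stop("degenerate affine: two voxel axes map to the same anatomical axis")
  paste(codes, collapse = "")
}

affine_from_orientation <- function(orientation, spacing_mm) {
  letters3 <- strsplit(orientation, "")[[1]]
  aff <- diag(4)
  aff[1:3, 1:3] <- 0
  for (j in 1:3) {
    k <- which(vapply(.axis_letters, function(p) letters3[j] %in% p, logical(1)))
    sign <- if (letters3[j] == .axis_letters[[k]][1]) 1 else -1
    aff[k, j] <- sign * spacing_mm[j]
  }
  aff
}

#' Read a CT volume or binary mask from NIfTI
#'
#' Voxel spacing and anatomical orientation are decoded from the NIfTI
#' affine. The orientation is reported as found; volumes are *not* silently
#' reordered — use [canonicalize()] before any measurement. Mask values are
#' binarized at 0.5.
#'
#' @param path path to a `.nii` or `.nii.gz` file holding a single-channel 3D
#'   image.
#' @return A [ct_volume()] (for `read_volume`) or [binary_mask()]
#'   (for `read_mask`).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    dim(img) <- d[1:3]
  } else if (length(d) != 3L) {
    stop("expected a 3D single-channel volume, got dimensions ",
         paste(d, collapse = "x"))
  }
  affine <- RNifti::xform(img)
  # NIfTI headers store float32; snap to 7 significant digits so spacings
  # like 0.7 survive the round-trip exactly
  spacing <- signif(sqrt(colSums(affine[1:3, 1:3]^2)), 7)
  check_spacing(spacing)
  ct_volume(as.array(img), spacing_mm = spacing,
            orientation = orientation_from_affine(affine))
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  binary_mask(vol$data > 0.5, spacing_mm = vol$spacing_mm,
              orientation = vol$orientation)
}

#' Write a CT volume or mask as NIfTI-1
#'
#' The affine encodes spacing and orientation; masks are written as uint8.
#' @param x `ct_volume` or `binary_mask`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(x, path) {
  arr <- if (inherits(x, "binary_mask")) {
    a <- array(as.integer(x$data), dim = dim(x$data))
    a
  } else {
    x$data
  }
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, x$spacing_mm)
  aff <- affine_from_orientation(x$orientation, x$spacing_mm)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

flip_axis <- function(arr, axis) {
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- rev(seq_len(dim(arr)[axis]))
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

#' Reorient a volume or mask to the canonical LPS axis order
#'
#' Permutes and flips axes so that axis 1 increases toward patient-left,
#' axis 2 toward posterior and axis 3 toward superior (orientation `"LPS"`).
#' Under this convention the "leftmost" liver pixel — the minimum index along
#' axis 1 — is the lateral margin of the right hepatic lobe (image-left under
#' the radiological display convention). Voxel values are untouched and the
#' operation is idempotent.
#'
#' @param x `ct_volume` or `binary_mask`.
#' @return The same type of object in `"LPS"` orientation.
#' @export
canonicalize <- function(x) {
  check_orientation(x$orientation)
  letters3 <- strsplit(x$orientation, "")[[1]]
  world <- vapply(letters3, function(l)
    which(vapply(.axis_letters, function(p) l %in% p, logical(1))), numeric(1))
  perm <- order(world)              # voxel axis that carries world axis k
  arr <- aperm(x$data, perm)
  spacing <- x$spacing_mm[perm]
  letters3 <- letters3[perm]
  target <- c("L", "P", "S")
  for (k in 1:3) {
    if (letters3[k] != target[k]) {
      arr <- flip_axis(arr, k)
      letters3[k] <- target[k]
    }
  }
  if (inherits(x, "binary_mask"))
    binary_mask(arr, spacing_mm = spacing, orientation = "LPS")
  else
    ct_volume(arr, spacing_mm = spacing, orientation = "LPS")
}

resample_axis_coords <- function(n_in, sp_in, sp_out) {
  n_out <- floor((n_in - 1) * sp_in / sp_out + 1e-9) + 1
  (seq_len(n_out) - 1) * sp_out / sp_in   # 0-based fractional input index
}

#' Resample to a target voxel spacing
#'
#' CT volumes are resampled with trilinear interpolation, masks with
#' nearest-neighbor (then re-binarized), following common practice for label
#' images. Output grids are aligned at the first-voxel center; the output
#' extent never exceeds the input extent, so no extrapolation occurs and the
#' physical extent is preserved to within one voxel per axis. The default
#' target is the 0.7 x 0.7 x 2.5 mm grid on which the ROI geometry defaults
#' are defined.
#'
#' @param x `ct_volume` or `binary_mask` in canonical orientation.
#' @param target_spacing_mm numeric length-3 target spacing, default
#'   `c(0.7, 0.7, 2.5)`.
#' @return The same type of object at the target spacing.
#' @export
resample <- function(x, target_spacing_mm = c(0.7, 0.7, 2.5)) {
  check_spacing(target_spacing_mm)
  d <- dim(x$data)
  if (max(abs(x$spacing_mm - target_spacing_mm)) < 1e-9)
    return(x)
  coords <- lapply(1:3, function(ax)
    resample_axis_coords(d[ax], x$spacing_mm[ax], target_spacing_mm[ax]))
  if (inherits(x, "binary_mask")) {
    idx <- lapply(1:3, function(ax) pmin(pmax(round(coords[[ax]]) + 1, 1), d[ax]))
    out <- x$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    return(binary_mask(out, spacing_mm = target_spacing_mm,
                       orientation = x$orientation))
  }
  out_dim <- vapply(coords, length, integer(1))
  i0 <- list(); frac <- list()
  for (ax in 1:3) {
    f <- floor(coords[[ax]])
    f <- pmin(pmax(f, 0), d[ax] - 1)
    i0[[ax]] <- as.integer(f) + 1L
    frac[[ax]] <- pmin(pmax(coords[[ax]] - f, 0), 1)
  }
  i1 <- lapply(1:3, function(ax) pmin(i0[[ax]] + 1L, d[ax]))
  out <- array(0, dim = out_dim)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- if (cx == 0) i0[[1]] else i1[[1]]
    iy <- if (cy == 0) i0[[2]] else i1[[2]]
    iz <- if (cz == 0) i0[[3]] else i1[[3]]
    wx <- if (cx == 0) 1 - frac[[1]] else frac[[1]]
    wy <- if (cy == 0) 1 - frac[[2]] else frac[[2]]
    wz <- if (cz == 0) 1 - frac[[3]] else frac[[3]]
    w <- outer(outer(wx, wy), wz)
    out <- out + x$data[ix, iy, iz, drop = FALSE] * w
  }
  ct_volume(out, spacing_mm = target_spacing_mm, orientation = x$orientation)
}

#' Keep only the largest connected component of a mask
#'
#' Standard postprocessing for organ segmentations: spurious disconnected
#' blobs are removed, leaving the single largest component under
#' 26-connectivity. Ties are broken deterministically in favor of the
#' component containing the smallest raster index.
#'
#' @param mask a nonempty `binary_mask`.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return A `binary_mask` with exactly one connected component.
#' @export
largest_component <- function(mask, connectivity = 26) {
  if (!any(mask$data)) stop("empty segmentation")
  labels <- cpp_label_components(as.vector(mask$data), dim(mask$data),
                                 as.integer(connectivity))
  counts <- tabulate(labels)
  # labels are assigned in raster order of component seeds, so the smallest
  # label among maximal counts is the smallest-min-raster-index tie-break
  keep <- which(counts == max(counts))[1]
  out <- array(labels == keep, dim = dim(mask$data))
  binary_mask(out, spacing_mm = mask$spacing_mm, orientation = mask$orientation)
}

#' Per-slice cross-sectional area of a mask
#'
#' For each axial slice (third axis, canonical orientation) intersecting the
#' mask, the in-plane foreground area in mm^2: pixel count times in-plane
#' pixel area.
#'
#' @param mask a `binary_mask` in canonical orientation.
#' @return A data.frame with columns `slice` (1-based index) and `area_mm2`,
#'   one row per slice containing mask pixels; zero rows for an empty mask.
#' @export
slice_area_profile <- function(mask) {
  counts <- apply(mask$data, 3, sum)
  px_area <- mask$spacing_mm[1] * mask$spacing_mm[2]
  hit <- which(counts > 0)
  data.frame(slice = hit, area_mm2 = counts[hit] * px_area)
}
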