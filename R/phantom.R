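#' Specification of a synthetic chest-CT liver phantom
#'
#' The phantom emulates the liver as seen on an unenhanced chest CT that has
#' been resampled to the canonical 0.7 x 0.7 x 2.5 mm grid: an ellipsoidal
#' parenchyma compartment at a configurable mean attenuation with additive
#' Gaussian voxel noise, straight cylindrical vessel tubes at a higher
#' attenuation threaded through the liver interior, and a uniform soft-tissue
#' background. Ground truth (compartment means, liver and vessel masks) is
#' returned alongside the volume, so estimator bias can be measured exactly.
#'
#' The default parenchymal mean of 56.33 HU matches a typical non-steatotic
#' adult cohort mean; a steatotic phantom is obtained by setting
#' `parenchyma_mu_hu` below 40. With `vessel_placement = "central"` no vessel
#' voxel is rasterized within `central_margin_mm` of the liver's leftmost
#' margin along the patient-left axis, emulating the observation that
#' hepatic veins and other non-parenchymal structures concentrate toward the
#' liver center while the lateral margin is clean parenchyma. For the
#' default ROI geometry (center 20 mm from the leftmost pixel, disc radius
#' ~7.98 mm) the ROI disc reaches ~28 mm from the margin, so the exclusion
#' must be at least `center_offset_mm + radius_mm` for ROIs to be
#' vessel-free by construction; the default of 30 mm covers this with a
#' 2 mm guard.
#'
#' @param grid_shape integer length-3 voxel counts per axis.
#' @param spacing_mm voxel spacing in mm (default `c(0.7, 0.7, 2.5)`).
#' @param liver_center_mm ellipsoid center in mm from the first voxel center;
#'   `NULL` places it at the central voxel of the grid.
#' @param liver_semiaxes_mm ellipsoid semi-axes in mm.
#' @param parenchyma_mu_hu mean parenchymal attenuation (HU).
#' @param noise_sd_hu Gaussian voxel noise SD (HU), `>= 0`.
#' @param vessel_delta_hu vessel attenuation offset above parenchyma (HU).
#' @param vessel_fraction target fraction of liver voxels occupied by
#'   vessels, in `[0, 0.3]`.
#' @param vessel_radius_mm cylinder radius of vessel tubes (mm).
#' @param vessel_placement `"central"` (vessels kept away from the leftmost
#'   margin) or `"uniform"` (chords anywhere in the liver).
#' @param central_margin_mm exclusion distance from the leftmost liver margin
#'   for `"central"` placement (mm).
#' @param background_hu uniform attenuation outside the liver.
#' @param seed integer RNG seed; fully determines the phantom.
#' @return A `phantom_spec` object (validated list).
#' @export
phantom_spec <- function(grid_shape = c(192L, 160L, 40L),
                         spacing_mm = c(0.7, 0.7, 2.5),
                         liver_center_mm = NULL,
                         liver_semiaxes_mm = c(60, 45, 42),
                         parenchyma_mu_hu = 56.33,
                         noise_sd_hu = 10,
                         vessel_delta_hu = 45,
                         vessel_fraction = 0.05,
                         vessel_radius_mm = 3,
                         vessel_placement = c("central", "uniform"),
                         central_margin_mm = 30,
                         background_hu = 20,
                         seed = 1L) {
  vessel_placement <- match.arg(vessel_placement)
  grid_shape <- as.integer(grid_shape)
  check_spacing(spacing_mm)
  if (is.null(liver_center_mm))
    liver_center_mm <- (grid_shape %/% 2) * spacing_mm
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            length(liver_center_mm) == 3L, length(liver_semiaxes_mm) == 3L)
  if (any(liver_semiaxes_mm <= 0)) stop("liver semi-axes must be positive")
  if (noise_sd_hu < 0) stop("noise_sd_hu must be >= 0")
  if (vessel_fraction < 0 || vessel_fraction > 0.3)
    stop("vessel_fraction must lie in [0, 0.3]")
  if (vessel_radius_mm <= 0) stop("vessel_radius_mm must be positive")
  extent <- (grid_shape - 1) * spacing_mm
  axis_names <- c("axis 1 (left-right)", "axis 2 (anterior-posterior)",
                  "axis 3 (superior-inferior)")
  for (ax in 1:3) {
    if (liver_center_mm[ax] - liver_semiaxes_mm[ax] < 0 ||
        liver_center_mm[ax] + liver_semiaxes_mm[ax] > extent[ax])
      stop("liver ellipsoid extends beyond the grid along ", axis_names[ax])
  }
  structure(list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
                 liver_center_mm = as.numeric(liver_center_mm),
                 liver_semiaxes_mm = as.numeric(liver_semiaxes_mm),
                 parenchyma_mu_hu = parenchyma_mu_hu,
                 noise_sd_hu = noise_sd_hu,
                 vessel_delta_hu = vessel_delta_hu,
                 vessel_fraction = vessel_fraction,
                 vessel_radius_mm = vessel_radius_mm,
                 vessel_placement = vessel_placement,
                 central_margin_mm = central_margin_mm,
                 background_hu = background_hu,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic liver phantom with ground truth
#'
#' Rasterizes the ellipsoidal liver of a [phantom_spec()], threads vessel
#' tubes through its interior until the target vessel fraction is met (the
#' last tube is trimmed along its axis so the realized fraction matches the
#' target to within one voxel), and fills compartments with
#' `Normal(parenchyma_mu_hu, noise_sd_hu)` parenchyma and
#' `Normal(parenchyma_mu_hu + vessel_delta_hu, noise_sd_hu)` vessels on a
#' uniform background. Equal specs (including seed) give bit-identical
#' output.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` (a [ct_volume()]) and `truth`, where
#'   `truth` holds `parenchyma_mean_hu` (the specified compartment mean),
#'   `realized_vessel_fraction`, `liver_mask` and `vessel_mask` (both
#'   [binary_mask()]; the vessel mask is a subset of the liver mask).
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(64, 56, 16),
#'                                     liver_semiaxes_mm = c(18, 15, 14),
#'                                     seed = 7))
#' measure_volumetric(ph$volume, ph$truth$liver_mask)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  sp <- spec$spacing_mm
  cx <- spec$liver_center_mm
  ax <- spec$liver_semiaxes_mm
  x <- ((seq_len(d[1]) - 1) * sp[1] - cx[1]) / ax[1]
  y <- ((seq_len(d[2]) - 1) * sp[2] - cx[2]) / ax[2]
  z <- ((seq_len(d[3]) - 1) * sp[3] - cx[3]) / ax[3]
  liver <- outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
  n_liver <- sum(liver)
  if (n_liver == 0L) stop("degenerate phantom: liver contains no voxels")

  vessel <- with_local_seed(spec$seed, {
    rasterize_vessels(liver, spec)
  })

  hu <- array(spec$background_hu, dim = d)
  liver_idx <- which(liver)
  noise <- with_local_seed(spec$seed + 1L, {
    if (spec$noise_sd_hu > 0) rnorm(n_liver, 0, spec$noise_sd_hu) else
      numeric(n_liver)
  })
  hu[liver_idx] <- spec$parenchyma_mu_hu + noise
  vessel_idx <- which(vessel)
  hu[vessel_idx] <- hu[vessel_idx] + spec$vessel_delta_hu

  list(volume = ct_volume(hu, spacing_mm = sp, orientation = "LPS"),
       truth = list(parenchyma_mean_hu = spec$parenchyma_mu_hu,
                    realized_vessel_fraction = length(vessel_idx) / n_liver,
                    liver_mask = binary_mask(liver, spacing_mm = sp,
                                             orientation = "LPS"),
                    vessel_mask = binary_mask(vessel, spacing_mm = sp,
                                              orientation = "LPS")))
}

# Straight cylinders along randomized interior chords; "central" placement
# restricts vessels to liver at least central_margin_mm right of the leftmost
# liver margin along axis 1. The final cylinder is trimmed along its chord so
# the realized vessel voxel count equals round(vessel_fraction * n_liver).
rasterize_vessels <- function(liver, spec) {
  d <- dim(liver)
  sp <- spec$spacing_mm
  vessel <- array(FALSE, dim = d)
  n_liver <- sum(liver)
  target <- round(spec$vessel_fraction * n_liver)
  if (target == 0L) return(vessel)

  allowed <- liver
  if (spec$vessel_placement == "central") {
    occ <- which(apply(liver, 1, any))
    leftmost_mm <- (min(occ) - 1) * sp[1]
    xmm <- (seq_len(d[1]) - 1) * sp[1]
    allowed <- liver & array(rep(xmm >= leftmost_mm + spec$central_margin_mm,
                                 times = d[2] * d[3]), dim = d)
    if (!any(allowed))
      stop("central placement leaves no room for vessels; ",
           "reduce central_margin_mm or enlarge the liver")
  }
  allowed_idx <- which(allowed)
  coords_of <- function(idx) {
    k <- arrayInd(idx, d)
    sweep(k - 1, 2, sp, `*`)
  }
  have <- 0L
  for (iter in seq_len(500L)) {
    if (have >= target) break
    ends <- coords_of(sample(allowed_idx, 2L))
    p0 <- ends[1, ]; p1 <- ends[2, ]
    v <- p1 - p0
    len2 <- sum(v^2)
    if (len2 < 1e-6) next
    r <- spec$vessel_radius_mm
    lo <- pmax(floor(pmin(p0, p1) - r) , 0)
    hi <- pmin(ceiling(pmax(p0, p1) + r), (d - 1) * sp)
    ii <- seq(floor(lo[1] / sp[1]), ceiling(hi[1] / sp[1])) + 1
    jj <- seq(floor(lo[2] / sp[2]), ceiling(hi[2] / sp[2])) + 1
    kk <- seq(floor(lo[3] / sp[3]), ceiling(hi[3] / sp[3])) + 1
    ii <- ii[ii >= 1 & ii <= d[1]]
    jj <- jj[jj >= 1 & jj <= d[2]]
    kk <- kk[kk >= 1 & kk <= d[3]]
    g <- expand.grid(i = ii, j = jj, k = kk)
    q <- cbind((g$i - 1) * sp[1], (g$j - 1) * sp[2], (g$k - 1) * sp[3])
    t_par <- ((q[, 1] - p0[1]) * v[1] + (q[, 2] - p0[2]) * v[2] +
                (q[, 3] - p0[3]) * v[3]) / len2
    t_par <- pmin(pmax(t_par, 0), 1)
    dx <- q[, 1] - (p0[1] + t_par * v[1])
    dy <- q[, 2] - (p0[2] + t_par * v[2])
    dz <- q[, 3] - (p0[3] + t_par * v[3])
    inside <- dx * dx + dy * dy + dz * dz <= r * r
    if (!any(inside)) next
    lin <- (g$k[inside] - 1L) * d[1] * d[2] + (g$j[inside] - 1L) * d[1] +
      g$i[inside]
    lin <- lin[allowed[lin] & !vessel[lin]]
    if (length(lin) == 0L) next
    need <- target - have
    if (length(lin) > need) {
      # trim along the chord: keep the voxels nearest the p0 end
      kq <- arrayInd(lin, d)
      qq <- sweep(kq - 1, 2, sp, `*`)
      tt <- ((qq[, 1] - p0[1]) * v[1] + (qq[, 2] - p0[2]) * v[2] +
               (qq[, 3] - p0[3]) * v[3]) / len2
      lin <- lin[order(tt)][seq_len(need)]
    }
    vessel[lin] <- TRUE
    have <- have + length(lin)
  }
  vessel
}

#' Perturb a binary mask for metric testing
#'
#' Produces controlled degradations of a segmentation so overlap and surface
#' metrics can be exercised against known answers: morphological dilation or
#' erosion (6-connected structuring element, one voxel per `magnitude` step),
#' a rigid shift along the patient-left axis, or the addition of a spurious
#' disconnected blob (`"drop_component"`) that largest-component filtering
#' should remove.
#'
#' @param mask a nonempty [binary_mask()].
#' @param mode one of `"dilate"`, `"erode"`, `"shift"`, `"drop_component"`.
#' @param magnitude perturbation size in voxels (iterations, shift distance,
#'   or blob side length). `0` returns the mask unchanged for
#'   `dilate`/`erode`/`shift`.
#' @param seed RNG seed (used by `"drop_component"` blob placement).
#' @return A [binary_mask()] on the same grid.
#' @export
perturb_mask <- function(mask, mode = c("dilate", "erode", "shift",
                                        "drop_component"),
                         magnitude = 1L, seed = 1L) {
  mode <- match.arg(mode)
  if (!any(mask$data)) stop("mask is empty")
  magnitude <- as.integer(magnitude)
  if (magnitude < 0) stop("magnitude must be >= 0")
  arr <- mask$data
  d <- dim(arr)
  out <- switch(mode,
    dilate = {
      for (i in seq_len(magnitude)) arr <- dilate6(arr)
      arr
    },
    erode = {
      for (i in seq_len(magnitude)) arr <- erode6(arr)
      arr
    },
    shift = shift_array(arr, axis = 1L, by = magnitude),
    drop_component = with_local_seed(seed, add_spurious_blob(arr, magnitude))
  )
  if (!any(out))
    stop("perturbation emptied the mask (mode ", mode, ", magnitude ",
         magnitude, ")")
  binary_mask(out, spacing_mm = mask$spacing_mm,
              orientation = mask$orientation)
}

shift_array <- function(arr, axis, by) {
  if (by == 0L) return(arr)
  d <- dim(arr)
  out <- array(FALSE, dim = d)
  n <- d[axis]
  if (by >= n) return(out)
  src <- seq_len(n - by)
  dst <- src + by
  idx_src <- rep(list(quote(expr = )), 3); idx_src[[axis]] <- src
  idx_dst <- rep(list(quote(expr = )), 3); idx_dst[[axis]] <- dst
  do.call(`[<-`, c(list(out), idx_dst,
                   list(value = do.call(`[`, c(list(arr), idx_src,
                                               list(drop = FALSE))))))
}

neighbor_stack <- function(arr, op) {
  out <- arr
  for (axis in 1:3) {
    for (by in c(-1L, 1L)) {
      shifted <- shift_any(arr, axis, by)
      out <- if (op == "or") out | shifted else out & shifted
    }
  }
  out
}

shift_any <- function(arr, axis, by) {
  if (by > 0) return(shift_array(arr, axis, by))
  # negative shift: flip, shift, flip back
  flip_axis(shift_array(flip_axis(arr, axis), axis, -by), axis)
}

dilate6 <- function(arr) neighbor_stack(arr, "or")
erode6 <- function(arr) neighbor_stack(arr, "and")

add_spurious_blob <- function(arr, magnitude) {
  d <- dim(arr)
  side <- max(1L, magnitude)
  # candidate corner positions where a side^3 cube is fully background and
  # not 26-adjacent to the mask
  halo <- dilate6(dilate6(arr))
  ok <- FALSE
  for (attempt in seq_len(200L)) {
    corner <- vapply(1:3, function(ax) sample.int(max(1L, d[ax] - side), 1L),
                     integer(1))
    ii <- corner[1]:(corner[1] + side - 1L)
    jj <- corner[2]:(corner[2] + side - 1L)
    kk <- corner[3]:(corner[3] + side - 1L)
    if (!any(halo[ii, jj, kk])) { ok <- TRUE; break }
  }
  if (!ok) stop("no room to place a spurious blob of side ", side)
  arr[ii, jj, kk] <- TRUE
  arr
}

#' Write a generated phantom to disk
#'
#' Writes the CT volume, liver mask and vessel mask as NIfTI files plus a
#' JSON sidecar with the ground-truth record, as consumed by the CLI.
#'
#' @param phantom a list as returned by [generate_phantom()].
#' @param dir output directory (created if missing).
#' @param prefix file name prefix, default `"phantom"`.
#' @return Invisibly, the named vector of written paths.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(ct = file.path(dir, paste0(prefix, "_ct.nii.gz")),
             liver = file.path(dir, paste0(prefix, "_liver.nii.gz")),
             vessels = file.path(dir, paste0(prefix, "_vessels.nii.gz")),
             truth = file.path(dir, paste0(prefix, "_truth.json")))
  write_volume(phantom$volume, paths["ct"])
  write_volume(phantom$truth$liver_mask, paths["liver"])
  write_volume(phantom$truth$vessel_mask, paths["vessels"])
  jsonlite::write_json(
    list(parenchyma_mean_hu = phantom$truth$parenchyma_mean_hu,
         realized_vessel_fraction = phantom$truth$realized_vessel_fraction),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
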