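#' Parameters of the coarse liver segmentation
#'
#' @param quantile threshold quantile of the ramped projection (default 0.90).
#' @param opening_kernel_mm diameter of the spherical opening element, mm.
#' @param dilation_kernel_mm diameter of the final dilation element, mm.
#' @param ramp_floor minimum of the anterior-right ramp in `[0, 1)`; a
#'   non-zero floor suppresses the spleen without annihilating posterior-left
#'   liver tissue.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(quantile = 0.90, opening_kernel_mm = 10,
                                dilation_kernel_mm = 5, ramp_floor = 0.25) {
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  if (opening_kernel_mm <= 0 || dilation_kernel_mm <= 0)
    stop("kernel sizes must be positive")
  if (ramp_floor < 0 || ramp_floor >= 1) stop("ramp_floor must be in [0, 1)")
  structure(list(quantile = quantile, opening_kernel_mm = opening_kernel_mm,
                 dilation_kernel_mm = dilation_kernel_mm,
                 ramp_floor = ramp_floor),
            class = "segmentation_params")
}

#' Mean intensity projection over the phases of a series
#'
#' Contrast agent accumulates in liver (and spleen) over the exam, so the
#' temporal mean is bright in those organs.
#'
#' @param series a [dce_series()] with all phases on one grid.
#' @return A `dce_volume` of voxelwise means.
#' @export
mean_intensity_projection <- function(series) {
  acc <- series$phases[[1L]]$data
  if (length(series$phases) > 1L)
    for (p in series$phases[-1L]) acc <- acc + p$data
  new_volume(acc / length(series$phases), series$phases[[1L]]$affine)
}

#' Anterior-right linear ramp image
#'
#' Value `ramp_floor + (1 - ramp_floor) * (x_right + y_anterior) / 2`, where
#' each normalized coordinate runs 0 to 1 across the world-space extent:
#' maximum 1 at the most anterior-right corner, minimum `ramp_floor` at the
#' most posterior-left corner, constant craniocaudally. Multiplying the mean
#' projection by this ramp emphasizes the liver over the spleen.
#'
#' @param geometry a `dce_volume` supplying grid and affine.
#' @param ramp_floor ramp minimum in `[0, 1)`.
#' @return A `dce_volume`.
#' @export
ramp_image <- function(geometry, ramp_floor = 0.25) {
  w <- grid_world_coords(geometry)
  norm01 <- function(v) {
    r <- range(v)
    if (r[2] - r[1] < .Machine$double.eps) return(rep(0.5, length(v)))
    (v - r[1]) / (r[2] - r[1])
  }
  val <- ramp_floor + (1 - ramp_floor) * (norm01(w[, 1]) + norm01(w[, 2])) / 2
  new_volume(array(val, geometry$dim), geometry$affine)
}

# integer voxel offsets of an ellipsoid with physical diameter `mm`
sphere_offsets <- function(mm, spacing) {
  r <- mm / 2
  rv <- pmax(floor(r / spacing), 0)
  g <- expand.grid(x = -rv[1]:rv[1], y = -rv[2]:rv[2], z = -rv[3]:rv[3])
  keep <- (g$x * spacing[1] / r)^2 + (g$y * spacing[2] / r)^2 +
          (g$z * spacing[3] / r)^2 <= 1
  as.matrix(g[keep, , drop = FALSE])
}

# near-uniform unit directions on the sphere (Fibonacci lattice)
fibonacci_directions <- function(n = 162L) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# rasterized convex hull of the TRUE voxels of a binary array, by half-space
# testing of voxel centers against direction-sampled supporting planes
convex_hull_mask <- function(mask, geometry, n_dirs = 162L) {
  fg <- which(mask)
  if (!length(fg)) stop("empty mask has no convex hull")
  pts <- grid_world_coords(geometry)
  D <- fibonacci_directions(n_dirs)
  proj_fg <- pts[fg, , drop = FALSE] %*% t(D)
  h <- apply(proj_fg, 2, max)
  # hull is inside the foreground bounding box: only test those voxels
  d <- geometry$dim
  vox <- arrayInd(fg, d)
  lo <- apply(vox, 2, min)
  hi <- apply(vox, 2, max)
  inbox <- as.vector(outer(seq_len(d[1]) >= lo[1] & seq_len(d[1]) <= hi[1],
                           outer(seq_len(d[2]) >= lo[2] & seq_len(d[2]) <= hi[2],
                                 seq_len(d[3]) >= lo[3] & seq_len(d[3]) <= hi[3])))
  cand <- which(inbox > 0)
  eps <- 1e-9 * max(abs(pts))
  ok <- rep(TRUE, length(cand))
  for (start in seq(1, n_dirs, by = 16L)) {
    cols <- start:min(start + 15L, n_dirs)
    pr <- pts[cand, , drop = FALSE] %*% t(D[cols, , drop = FALSE])
    ok <- ok & rowSums(sweep(pr, 2, h[cols] + eps, ">")) == 0
  }
  out <- rep(FALSE, prod(d))
  out[cand[ok]] <- TRUE
  out
}

#' Coarse automatic liver segmentation
#'
#' Seven-step pipeline on a grid-normalized series: mean intensity
#' projection, multiplication by the anterior-right ramp, threshold at the
#' `quantile` quantile of all voxel values, morphological opening with a
#' spherical element of diameter `opening_kernel_mm`, 3D convex hull of the
#' remaining foreground, and dilation with a spherical element of diameter
#' `dilation_kernel_mm`. The result is a deliberately coarse liver region
#' intended to mask the rigid preregistration, not an anatomical liver
#' segmentation.
#'
#' @param series a [dce_series()].
#' @param params a [segmentation_params()].
#' @return Binary (0/1) `dce_volume` mask.
#' @export
segment_liver <- function(series, params = segmentation_params()) {
  geom <- series$phases[[1L]]
  proj <- mean_intensity_projection(series)
  ramped <- proj$data * ramp_image(geom, params$ramp_floor)$data
  thr <- quantile(ramped, params$quantile, names = FALSE)
  mask <- as.vector(ramped > thr)

  off_open <- sphere_offsets(params$opening_kernel_mm, geom$spacing)
  opened <- cpp_morph(cpp_morph(mask, geom$dim, off_open, FALSE),
                      geom$dim, off_open, TRUE)
  if (!any(opened))
    stop("empty mask after opening: degenerate input series")
  hull <- convex_hull_mask(opened, geom)
  off_dil <- sphere_offsets(params$dilation_kernel_mm, geom$spacing)
  dilated <- cpp_morph(hull, geom$dim, off_dil, TRUE)
  new_volume(array(as.numeric(dilated), geom$dim), geom$affine)
}

#' Overlap statistics between two binary masks
#'
#' @param mask,reference binary `dce_volume`s on one grid.
#' @return List with `dice` and `coverage` (fraction of reference voxels
#'   inside `mask`).
#' @export
mask_overlap <- function(mask, reference) {
  a <- mask$data > 0
  b <- reference$data > 0
  inter <- sum(a & b)
  list(dice = 2 * inter / (sum(a) + sum(b)), coverage = inter / sum(b))
}
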