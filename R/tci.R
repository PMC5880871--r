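#' An anterior-posterior line for time-cut images
#'
#' @param x_mm left-right world coordinate of the line, mm.
#' @param z_mm craniocaudal world coordinate (axial slice position), mm.
#' @return A `tci_line`.
#' @export
tci_line <- function(x_mm, z_mm) {
  structure(list(x_mm = x_mm, z_mm = z_mm), class = "tci_line")
}

#' Extract a time-cut image
#'
#' Stacks the intensities along one fixed anterior-posterior one-voxel line
#' across all phases: column t of the output holds the line profile in phase
#' t. After a good motion correction, anatomical structures form straight
#' horizontal lines in the TCI.
#'
#' @param series a [dce_series()] (original or motion-corrected phases).
#' @param line a [tci_line()] inside the image bounds.
#' @return Matrix of size (line voxel count) x (number of phases).
#' @export
extract_tci <- function(series, line) {
  geom <- series$phases[[1L]]
  v <- world_to_voxel(c(line$x_mm, 0, line$z_mm), geom$affine)[1, ]
  i <- round(v[1]) + 1L
  k <- round(v[3]) + 1L
  if (i < 1L || i > geom$dim[1] || k < 1L || k > geom$dim[3])
    stop("TCI line outside the image bounds")
  out <- vapply(series$phases, function(p) p$data[i, , k],
                numeric(geom$dim[2]))
  colnames(out) <- series$labels
  out
}

#' Default TCI line placement from a liver mask
#'
#' Selects the axial slice with maximal in-mask cross-sectional area and
#' places three anterior-posterior lines at the 25%, 50% and 75% left-right
#' quantiles of the mask within that slice (left, center and right of the
#' liver).
#'
#' @param liver_mask binary `dce_volume`.
#' @return List of three [tci_line()]s.
#' @export
default_tci_lines <- function(liver_mask) {
  m <- liver_mask$data > 0
  if (!any(m)) stop("empty liver mask")
  area <- apply(m, 3, sum)
  k <- which.max(area)
  sl <- m[, , k]
  xs <- which(rowSums(sl) > 0)
  q <- quantile(xs, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  z_mm <- voxel_to_world(c(0, 0, k - 1), liver_mask$affine)[1, 3]
  lapply(q, function(xi) {
    x_mm <- voxel_to_world(c(xi - 1, 0, 0), liver_mask$affine)[1, 1]
    tci_line(x_mm, z_mm)
  })
}

#' Mean absolute column-to-column difference of a TCI
#'
#' A simple temporal-consistency score: motion shows up as differences
#' between adjacent phase columns.
#'
#' @param tci matrix from [extract_tci()].
#' @return Scalar mean absolute difference.
#' @export
tci_temporal_roughness <- function(tci) {
  if (ncol(tci) < 2L) return(0)
  mean(abs(tci[, -1L, drop = FALSE] - tci[, -ncol(tci), drop = FALSE]))
}
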