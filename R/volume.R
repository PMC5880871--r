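#' 3D image volume with world geometry
#'
#' A `dce_volume` holds a 3D scalar array together with a 4x4 voxel-to-world
#' affine (RAS+, mm; 0-based voxel indices map voxel centers to world
#' coordinates). Voxel spacing is derived from the affine column norms.
#'
#' @param data numeric 3D array of intensities.
#' @param affine 4x4 voxel-to-world matrix (RAS+, mm).
#' @return An object of class `dce_volume` with elements `data`, `affine`,
#'   `spacing` and `dim`.
#' @export
new_volume <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got ", length(dim(data)), " dims")
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  if (abs(det(affine)) < .Machine$double.eps * 64)
    stop("affine is singular (non-invertible)")
  if (!all(is.finite(data))) stop("volume data contains non-finite values")
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(spacing <= 0)) stop("voxel spacing must be positive on all axes")
  structure(list(data = data, affine = affine, spacing = spacing,
                 dim = dim(data)),
            class = "dce_volume")
}

#' @export
print.dce_volume <- function(x, ...) {
  cat("<dce_volume> ", paste(x$dim, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Build a simple axis-aligned affine
#'
#' @param spacing length-3 voxel spacing in mm.
#' @param origin world coordinate of voxel (0,0,0).
#' @return 4x4 affine matrix.
#' @export
make_affine <- function(spacing, origin = c(0, 0, 0)) {
  A <- diag(4)
  diag(A)[1:3] <- spacing
  A[1:3, 4] <- origin
  A
}

# voxel (0-based, N x 3) -> world (N x 3)
voxel_to_world <- function(vox, affine) {
  vox <- matrix(vox, ncol = 3)
  sweep(vox %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], "+")
}

# world (N x 3) -> voxel (0-based, N x 3)
world_to_voxel <- function(world, affine) {
  world <- matrix(world, ncol = 3)
  sweep(world, 2, affine[1:3, 4], "-") %*% t(solve(affine[1:3, 1:3]))
}

# world coordinates of every voxel center, N x 3, column-major voxel order
grid_world_coords <- function(vol) {
  d <- vol$dim
  vox <- cbind(rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
               rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
               rep(seq_len(d[3]) - 1L, each = d[1] * d[2]))
  voxel_to_world(vox, vol$affine)
}

#' Read a 3D NIfTI volume
#'
#' Reads a single 3D NIfTI file and returns a [new_volume()] with the
#' voxel-to-world affine taken from the file's sform/qform (NIfTI world
#' coordinates are RAS+ mm). 4D files are rejected; split them into one file
#' per phase first.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A `dce_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) d <- d[1:3]
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), "D; split 4D series into phases")
  A <- unclass(RNifti::xform(img))
  attributes(A) <- list(dim = dim(A))
  new_volume(array(as.numeric(img), dim = d), A)
}

#' Write a volume to NIfTI
#'
#' @param vol a `dce_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type, e.g. `"float"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "float") {
  img <- RNifti::asNifti(vol$data, datatype = datatype)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Ordered multi-phase DCE series
#'
#' Bundles the phase volumes of one DCE-MRI acquisition. All phases must share
#' one grid and affine (use [resample_to_reference()] first if they do not).
#' The fixed (registration target) phase defaults to the last one, the
#' late-venous phase in a standard 5-phase liver protocol.
#'
#' @param phases list of `dce_volume`, in temporal order.
#' @param labels character phase names; defaults to the standard 5-phase
#'   naming when 5 phases are given.
#' @param fixed_index index of the fixed phase (default: last).
#' @return A `dce_series` object.
#' @export
dce_series <- function(phases, labels = NULL, fixed_index = length(phases)) {
  if (length(phases) < 2L) stop("a DCE series needs at least 2 phases")
  if (!all(vapply(phases, inherits, logical(1), "dce_volume")))
    stop("phases must be dce_volume objects")
  ref <- phases[[1L]]
  same <- vapply(phases, function(p)
    identical(p$dim, ref$dim) && max(abs(p$affine - ref$affine)) < 1e-6, logical(1))
  if (!all(same)) stop("all phases must share one grid/affine; resample first")
  if (is.null(labels)) {
    labels <- if (length(phases) == 5L)
      c("native", "arterial", "portal-venous", "equilibrium", "late-venous")
    else paste0("phase", seq_along(phases))
  }
  if (length(labels) != length(phases)) stop("one label per phase required")
  if (fixed_index < 1L || fixed_index > length(phases)) stop("invalid fixed_index")
  structure(list(phases = phases, labels = labels, fixed_index = fixed_index),
            class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  cat("<dce_series> ", length(x$phases), " phases (",
      paste(x$labels, collapse = ", "), "), fixed = ",
      x$labels[x$fixed_index], "\n", sep = "")
  invisible(x)
}

#' Dense displacement field on a fixed grid
#'
#' Displacements are world-mm 3-vectors defined at the voxel centers of the
#' fixed image; the deformation is phi(x) = x + u(x), mapping fixed-domain
#' world points into the moving domain.
#'
#' @param u 4D array `dim(fixed) x 3` of mm displacements.
#' @param geometry a `dce_volume` (or its geometry) supplying grid and affine.
#' @return A `dce_field` object.
#' @export
new_field <- function(u, geometry) {
  if (length(dim(u)) != 4L || dim(u)[4] != 3L)
    stop("displacement field must be a (nx, ny, nz, 3) array")
  if (!all(dim(u)[1:3] == geometry$dim))
    stop("field grid does not match the fixed geometry")
  if (!all(is.finite(u))) stop("displacement field contains non-finite values")
  structure(list(u = u, affine = geometry$affine, spacing = geometry$spacing,
                 dim = geometry$dim),
            class = "dce_field")
}

#' Zero displacement field on a given geometry
#' @param geometry a `dce_volume`.
#' @return A `dce_field` of zeros.
#' @export
zero_field <- function(geometry) {
  new_field(array(0, c(geometry$dim, 3L)), geometry)
}

#' Read/write displacement fields as 4D NIfTI
#'
#' Fields are stored as a 4D NIfTI with 3 volumes (x, y, z world-mm
#' components on the fixed grid).
#'
#' @param path NIfTI file path.
#' @return `read_field()` returns a `dce_field`.
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L)
    stop("expected a 4D NIfTI with 3 components, got dims ", paste(d, collapse = "x"))
  A <- unclass(RNifti::xform(img))
  attributes(A) <- list(dim = dim(A))
  geom <- new_volume(array(0, d[1:3]), A)
  new_field(array(as.numeric(img), dim = d), geom)
}

#' @rdname read_field
#' @param field a `dce_field`.
#' @export
write_field <- function(field, path) {
  img <- RNifti::asNifti(field$u, datatype = "double")
  RNifti::sform(img) <- structure(field$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Resample a volume onto a reference grid
#'
#' Values are sampled from `vol` at the world positions of the reference
#' voxel centers; positions outside `vol`'s field of view receive `fill`.
#'
#' @param vol `dce_volume` to resample.
#' @param ref `dce_volume` providing the target grid and affine.
#' @param interpolation `"linear"` (trilinear) or `"nearest"`.
#' @param fill value for out-of-field-of-view voxels (default 0).
#' @return A `dce_volume` on `ref`'s grid.
#' @export
resample_to_reference <- function(vol, ref, interpolation = c("linear", "nearest"),
                                  fill = 0) {
  interpolation <- match.arg(interpolation)
  if (any(ref$dim < 1L)) stop("degenerate reference grid")
  w <- grid_world_coords(ref)
  v <- world_to_voxel(w, vol$affine)
  if (interpolation == "nearest") v <- round(v)
  s <- cpp_trilinear(as.numeric(vol$data), vol$dim, v, fill, FALSE)
  new_volume(array(s$value, ref$dim), ref$affine)
}

# block-mean downsampling by an integer factor per axis; affine updated so
# that new voxel centers sit at the mean of the averaged block centers
downsample_volume <- function(vol, factor = c(2L, 2L, 2L)) {
  factor <- rep_len(as.integer(factor), 3L)
  d <- vol$dim
  nd <- pmax(d %/% factor, 1L)
  factor <- ifelse(nd == 1L, d, factor) # degenerate axis: average everything
  a <- vol$data[seq_len(nd[1] * factor[1]),
                seq_len(nd[2] * factor[2]),
                seq_len(nd[3] * factor[3]), drop = FALSE]
  dim(a) <- c(factor[1], nd[1], factor[2], nd[2], factor[3], nd[3])
  out <- apply(a, c(2, 4, 6), mean)
  A <- vol$affine
  A2 <- A
  A2[1:3, 1:3] <- A[1:3, 1:3] %*% diag(factor)
  A2[1:3, 4] <- A[1:3, 4] + A[1:3, 1:3] %*% ((factor - 1) / 2)
  new_volume(array(out, nd), A2)
}

# trilinear interpolation of a field's displacement vectors at world points;
# returns an N x 3 matrix of mm displacements
field_at_world <- function(field, world) {
  v <- world_to_voxel(world, field$affine)
  n <- prod(field$dim)
  u <- matrix(field$u, nrow = n)
  ins <- NULL
  out <- matrix(0, nrow(v), 3)
  for (c in 1:3) {
    s <- cpp_trilinear(u[, c], field$dim, v, NA_real_, FALSE)
    out[, c] <- s$value
    ins <- s$inside
  }
  if (anyNA(out)) stop("point outside the displacement field domain")
  out
}

#' Apply a deformation to landmark-style world points
#'
#' Computes phi(x) = x + u(x) with `u` trilinearly interpolated at `world`.
#' With `field = NULL` the identity map is returned.
#'
#' @param field a `dce_field` or `NULL`.
#' @param world N x 3 matrix of world-mm points on the fixed domain.
#' @return N x 3 matrix of mapped world points.
#' @export
map_points <- function(field, world) {
  world <- matrix(world, ncol = 3)
  if (is.null(field)) return(world)
  world + field_at_world(field, world)
}
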