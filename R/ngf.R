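#' Normalized gradient fields distance
#'
#' NGF compares local gradient directions and is therefore robust to the
#' strong contrast changes between DCE phases. Per voxel,
#' `d(x) = 1 - (<gF,gM> + eta^2)^2 / ((|gF|^2 + eta^2) (|gM|^2 + eta^2))`,
#' with gradients by central differences in world mm; the distance is the
#' mean of `d` over the (masked) voxels, so it lies in `[0, 1]` and its scale
#' is grid-independent. The edge parameter `eta` (intensity units per mm)
#' damps the contribution of low-gradient (noise) regions: both numerator
#' and denominator carry `eta^2`, so flat regions contribute 0.
#'
#' @param fixed,moving_warped `dce_volume`s on one grid.
#' @param eta edge parameter, > 0.
#' @param mask optional binary `dce_volume`; the mean is restricted to mask
#'   voxels.
#' @return Scalar distance in `[0, 1]`.
#' @export
ngf_distance <- function(fixed, moving_warped, eta, mask = NULL) {
  stopifnot(eta > 0)
  if (!identical(fixed$dim, moving_warped$dim))
    stop("images must share one grid")
  gF <- cpp_gradient(as.numeric(fixed$data), fixed$dim, fixed$spacing)
  gM <- cpp_gradient(as.numeric(moving_warped$data), fixed$dim, fixed$spacing)
  sel <- if (is.null(mask)) rep(TRUE, prod(fixed$dim)) else as.vector(mask$data > 0)
  if (!any(sel)) stop("empty mask")
  cpp_ngf(gF, gM, eta, sel, FALSE)$value
}

#' Curvature regularization energy
#'
#' `S[u] = 1/2 * integral of sum_l (Laplacian u_l)^2 dx`, discretized with
#' second-order central differences in mm (a node on a boundary face
#' contributes zero along that axis, so affine displacements have exactly
#' zero energy) and the integral as a voxel-volume-weighted sum.
#'
#' @param field a `dce_field`.
#' @return Scalar energy, >= 0.
#' @export
curvature_energy <- function(field) {
  voxvol <- abs(det(field$affine[1:3, 1:3]))
  n <- prod(field$dim)
  u <- matrix(field$u, nrow = n)
  s <- 0
  for (l in 1:3) {
    v <- cpp_laplacian(u[, l], field$dim, field$spacing)
    s <- s + sum(v^2)
  }
  0.5 * voxvol * s
}

# --- deformable objective ---------------------------------------------------

# J[u] = NGF(F, M(x + u)) + alpha * S[u] / V, with V the fixed-domain volume
# so that alpha, like the NGF mean, is grid-independent. Returns value and
# exact gradient of the discretized objective.
deform_objective <- function(uvec, ctx) {
  n <- ctx$n
  U <- matrix(uvec, nrow = n)
  pts_w <- ctx$world + U
  pts_v <- sweep(pts_w, 2, ctx$mov_affine[1:3, 4], "-") %*% ctx$mov_ainv_t
  # clamped sampling keeps the objective continuous at the FOV edge; the
  # voxel selection is frozen per level solve (see freeze_selection)
  tri <- cpp_trilinear(ctx$mov_data, ctx$mov_dim, pts_v, 0, TRUE, TRUE)
  gM <- cpp_gradient(tri$value, ctx$dim, ctx$spacing)
  ngf <- cpp_ngf(ctx$gF, gM, ctx$eta, ctx$sel, TRUE)
  wM <- cpp_gradient_adjoint(ngf$dgM, ctx$dim, ctx$spacing)
  # chain rule through the trilinear interpolant: d voxel coord / d u = Ainv
  dD <- matrix(0, n, 3)
  for (l in 1:3)
    dD[, l] <- wM * (tri$grad[, 1] * ctx$mov_ainv_t[l, 1] +
                     tri$grad[, 2] * ctx$mov_ainv_t[l, 2] +
                     tri$grad[, 3] * ctx$mov_ainv_t[l, 3])
  S <- 0
  dS <- matrix(0, n, 3)
  for (l in 1:3) {
    v <- cpp_laplacian(U[, l], ctx$dim, ctx$spacing)
    S <- S + sum(v^2)
    dS[, l] <- cpp_laplacian_adjoint(v, ctx$dim, ctx$spacing)
  }
  S <- 0.5 * ctx$voxvol * S
  dS <- ctx$voxvol * dS
  list(value = ngf$value + ctx$alpha * S / ctx$volume,
       grad = as.numeric(dD + ctx$alpha / ctx$volume * dS),
       D = ngf$value, S = S)
}

make_deform_context <- function(fixed, moving, eta, alpha, mask = NULL) {
  n <- prod(fixed$dim)
  list(n = n, dim = fixed$dim, spacing = fixed$spacing,
       world = grid_world_coords(fixed),
       gF = cpp_gradient(as.numeric(fixed$data), fixed$dim, fixed$spacing),
       mov_data = as.numeric(moving$data), mov_dim = moving$dim,
       mov_affine = moving$affine,
       mov_ainv_t = t(solve(moving$affine[1:3, 1:3])),
       sel = if (is.null(mask)) rep(TRUE, n) else as.vector(mask$data > 0),
       eta = eta, alpha = alpha,
       voxvol = abs(det(fixed$affine[1:3, 1:3])),
       volume = n * abs(det(fixed$affine[1:3, 1:3])))
}

# freeze the NGF integration domain for one level solve: voxels whose mapped
# position under the initial displacement falls outside the moving FOV are
# excluded from the distance mean for the whole solve
freeze_selection <- function(ctx, uvec) {
  U <- matrix(uvec, nrow = ctx$n)
  pts_v <- sweep(ctx$world + U, 2, ctx$mov_affine[1:3, 4], "-") %*% ctx$mov_ainv_t
  tri <- cpp_trilinear(ctx$mov_data, ctx$mov_dim, pts_v, 0, FALSE, TRUE)
  ctx$sel <- ctx$sel & tri$inside
  if (!any(ctx$sel)) stop("empty voxel selection: no field-of-view overlap")
  ctx
}
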